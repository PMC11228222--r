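from,to,years,published_pct
ECIG_ONLY,SMOKING,3,25
ECIG_ONLY,SMOKING,5,27
NEVER,NEVER,5,69
NEVER,ECIG_ONLY,3,8
NEVER,SMOKING,3,6
NEVER,ECIG_ONLY,5,10
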