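state,NEVER,NONCURRENT,ECIG_ONLY,SMOKING
NEVER,92.9,0.9,4.0,2.2
NONCURRENT,0,79.6,12.2,8.3
ECIG_ONLY,0,26.6,59.1,14.3
SMOKING,0,15.3,10.9,73.8
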