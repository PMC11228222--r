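# Raw panel CSV data dictionary

One row per subject per interview. Columns:

| column | type | values |
|---|---|---|
| `subject_id` | id | opaque |
| `wave` | integer | 7-12 |
| `interview_time` | numeric | years since study start (decimal) |
| `interview_date` | date (optional) | ISO 8601, used by the calendar-window sensitivity filter |
| `age_years` | integer | 10-25 at the interview |
| `ecig_response` | enum | wave 7: `yes`, `no`; waves 8-12: `never`, `tried once or twice`, `past not now`, `less than monthly`, `monthly not weekly`, `at least weekly` |
| `smoke_response` | enum | `yes`, `no` |
| `sex` | enum | `male`, `female` |
| `ethnicity` | enum | `white`, `ethnic minority` |
| `household_income_monthly` | numeric | GBP per month, household net |
| `household_adults` | integer | >= 1 |
| `household_children_under14` | integer | >= 0 |
| `survey_weight` | numeric | >= 0 |

Current e-cigarette use is every response except `never` and `past not now`
(wave 7: `yes`). Current smoking is `smoke_response == "yes"`. Missing
nicotine responses drop the record; missing ethnicity or income drops the
subject; subjects observed at fewer than two waves are excluded.
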