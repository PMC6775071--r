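# CSV dialects (schema version 1)

All files are plain comma-separated text with a header row, read and
written by `readActivity`/`writeActivity`, `readDiary`/`writeDiary`,
`readCovariates`/`writeCovariates`, `readSnore`/`writeSnore`.

## activity.csv

| column | type | notes |
|---|---|---|
| subject_id | string | |
| timestamp | ISO-8601 local clock time, `YYYY-MM-DDTHH:MM:SS` (a space separator is also accepted) | strictly increasing within subject; 1-minute spacing within a day; no duplicates |
| count | non-negative integer | activity counts for the minute starting at `timestamp` |

## diary.csv

| column | type | notes |
|---|---|---|
| subject_id | string | |
| date | `YYYY-MM-DD` | the night's *evening-onset* date |
| bed_time | `HH:MM` | at/after 12:00 = that evening; before 12:00 = after midnight on the next calendar day |
| rise_time | `HH:MM` | first occurrence of this clock time after bed; equal to bed_time is rejected |

## covariates.csv

| column | type | notes |
|---|---|---|
| subject_id | string | unique |
| age | number | years |
| weight | number | kg |
| sex | `F` or `M` | any other code is rejected |
| cbpi | number | baseline CBPI pain sub-score |

## snore.csv

| column | type | notes |
|---|---|---|
| subject_id | string | |
| day | integer | assessment day (0 = baseline; schedule 0/14/21/28/35 under the default design) |
| item1 .. item6 | number | item scores (integer 0-10 under the default generator) |

A `condition` column is accepted and ignored on read.
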