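# Shipped fixtures

Transcribed contingency tables from a published colorectal-cancer staging
study comparing pre-surgical imaging stage calls against post-surgical
histopathological T stage:

- `table2_mr_staging.csv` - MR staging vs pathological staging, 146
  patients. Rows are the imaging call, columns the pathological stage.
- `table4_ct_staging.csv` - CT staging vs pathological staging, 98
  patients (a second cohort).
- `table1_cohort.csv` - cohort composition (sex counts per pathological
  stage group) for the MR cohort.

Known internal inconsistencies of the source tables, preserved as printed:
the sex counts sum to 88 men / 58 women while the study text says 86 / 60
(the table is followed here); the source's printed specificity and
coincidence denominators are not derivable from the contingency counts, so
`evaluate_cohort()` reports the standard one-vs-rest definitions computed
from the counts instead.
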