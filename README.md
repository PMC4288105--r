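# neurocds

A clinical-decision-support (CDS) engine for the first-line pharmacologic
management of neuropathic pain (NP), built as a reusable R package for
medical-informatics developers and researchers who want to study or
re-deploy this style of point-of-care advisory.

Neuropathic pain is managed with staged pharmacotherapy — first-line
tricyclic antidepressants (TCAs), SNRIs and gabapentinoids; second-line
opioids and tramadol; third-line agents such as carbamazepine or
citalopram — and a primary-care advisory must tailor its comments to the
patient's comorbidities and medication history without trying to dictate
care. `neurocds` implements the full architecture of such a system on
synthetic data:

* **Knowledge-base DSL** — clinical authors write derivation rules
  (`if (amitriptyline_tx || nortriptyline_tx) tca_tx = true;`) and
  conditional comments that route one text to several named interface
  locations, each under its own boolean condition with a sort order.
  The package parses, validates, pretty-prints and compiles this language
  (`parse_kb()`, `validate_kb()`, `compile_kb()`).
* **Evaluation engine** — rules run once in declaration order over
  boolean patient facts; fired comments are sorted within each location
  by order, ties by declaration (`evaluate()`). Any extracted fact can be
  overridden by the clinician and the plan re-runs in about a millisecond
  (`override_fact()`). A direct AST interpreter
  (`truth_table_reference()`) serves as an independent oracle.
* **EHR condensation** — a staging build condenses diagnosis and
  medication-order tables into per-patient comorbidity bitflags (ICD9
  prefix matching) and a closed five-year NP-medication lookback
  (`build_staging()`); current medications, fact publication and
  treatment-line classification are live queries (`current_np_meds()`,
  `facts_from_ehr()`, `classify_regimen()`).
* **Synthetic cohorts** — seeded, bit-reproducible EHR tables with
  controllable comorbidity prevalences and medication scenarios
  (`generate_cohort()`, `demo_patient()`).
* **Report assembly** — a sectioned single-screen advisory (header with
  provenance-labelled checkboxes, medications, ordered recommendations,
  expandable drug-class outline, scope warning, links) rendered as JSON,
  static HTML or plain text (`assemble_report()`, `render_report()`).

## Worked example

The bundled demo patient is a 67-year-old on amitriptyline with a
depression diagnosis (ICD9 311) in his chart:

```r
library(neurocds)
kb  <- np_demo_kb()                      # bundled KB + input/location config
dp  <- demo_patient("tca_depression")    # one-patient synthetic EHR
run <- cds_run(kb, dp, "DEMO1", dp$as_of)
cat(render_report(run$report, "text"))
```

```
Patient: ZZTEST,DEMO TCA   Age: 67   Sex: M
Comorbidities:
  [ ] heart_disease (extracted)
  [x] depression (extracted)
  ...
Current NP medications:
  amitriptyline (TCA, line 1) - 25 mg PO qhs
...
Comments/Recommendations:
  1. The presence of depression is not required for the analgesic effects
     of TCAs, although they may be particularly useful in patients with
     inadequately treated depression.
...
Treatment outline:
* TCA
    - The presence of depression is not required for the analgesic ...
```

The extraction layer set `amitriptyline_tx` and `depression_hx` from the
chart (checkbox provenance `extracted`); the rule derived `tca_tx`; and
the `TCA_depression` comment fired on both of its routes — into
Comments/Recommendations (order 7) and into the TCA outline panel
(order 5). Unchecking the depression box
(`cds_run(..., overrides = c(depression_hx = FALSE))`) removes both
placements on the instant re-evaluation; a patient currently on an opioid
alongside a first-line drug (`demo_patient("first_plus_second")`)
additionally gets the fixed scope note explaining that the advisory
covers first-line management only.

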