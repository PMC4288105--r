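---
title: "Methods: a knowledge-base driven advisory engine for neuropathic pain"
author: "neurocds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a knowledge-base driven advisory engine for neuropathic pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocds)
```

## The problem

Primary-care providers manage neuropathic pain (NP) with a staged
pharmacotherapy: first-line agents (tricyclic antidepressants, SNRIs,
gabapentinoids), then opioids/tramadol (second line), then other
anticonvulsants and antidepressants (third line), with escalation usually
warranting a neurology consult. A point-of-care advisory for this domain
must (1) pull the patient's comorbidities and medication history out of the
EHR fast enough to be usable mid-visit, (2) tailor non-prescriptive
comments to that patient, and (3) let the clinician correct any extracted
fact and see the advice update immediately.

`neurocds` is a reusable engine for that architecture. It separates four
concerns: a small knowledge-base (KB) language that clinical authors edit;
a compiler and evaluation engine; an EHR condensation ("staging") layer;
and a sectioned report assembler. A synthetic-cohort generator makes the
whole pipeline testable without any patient data.

## The knowledge-base language

A KB is a plain-text file with two kinds of declaration.

**Derivation rules** abstract raw medication facts into clinical concepts:

```
if (amitriptyline_tx || nortriptyline_tx) tca_tx = true;
```

**Conditional comments** route one text to one or more named interface
locations, each under its own condition and sort order:

```
Comment TCA_depression {
  Condition: tca_tx & depression_hx; Where: Recommendations (order: 7);
  Condition: depression_hx; Where: TCA_comments (order: 5);
  Text: "The presence of depression is not required ..."
}
```

The grammar is the smallest one covering both forms: rule statements
`if (<expr>) <var> = true|false; ...` (one or more literal assignments) and
comment blocks with one or more `Condition:`/`Where:` routes followed by a
quoted `Text:`. Both `||`/`|` and `&&`/`&` are accepted (clinical authors
use both spellings), `!` negates, precedence is not > and > or, `#` opens a
line comment, and `Text` strings are double-quoted, may span lines, and
escape quotes as `\"`. The language deliberately has no `else`, no
numerics, no dates: every condition is a pure boolean formula over
published facts, which keeps authoring simple and makes exhaustive
verification cheap.

The file itself declares nothing about its inputs. The set of *declared
inputs* (facts the extraction layer publishes) and the *location registry*
(which report locations exist) live in a YAML config, so the same KB can be
checked against different deployments.

### Static validation

`validate_kb()` returns a diagnostics table rather than failing fast:
undefined variables, inputs that are also rule targets, reads of a derived
variable before any rule assigns it, routes to unregistered locations
(each blocking), and never-satisfiable routes (warning). `compile_kb()`
refuses any KB with blocking diagnostics.

### Evaluation semantics

Compilation lowers each condition to a host-language expression once;
evaluation then:

1. binds every declared input (facts missing from the patient's set
   default to `FALSE` with a warning — absence of chart evidence reads as
   absent);
2. initialises every rule target to `FALSE`;
3. runs the rules once, in declaration order — assignments are literals,
   later rules may overwrite earlier targets, last write wins;
4. checks every comment route against the post-rule bindings and sorts the
   fired placements within each location ascending by `order`, ties broken
   by declaration order (a stable sort), with any comment appearing at
   most once per location.

Single-pass semantics mirror straight-line generated code; the
use-before-assignment diagnostic guarantees a valid KB cannot observe the
difference from fixpoint iteration. The same semantics are implemented a
second time as `truth_table_reference()`, a direct recursive interpreter
with an independently coded sort, used purely as a test oracle: for
randomly generated KBs the suite checks `evaluate(compile_kb(kb), x)`
against the reference on *all* `2^n` input assignments.

`override_fact()` models the clinician toggling a comorbidity checkbox:
the input takes the new value with provenance `override` and the plan is
simply re-run in full. At KB scale (tens of rules) a full re-evaluation
takes on the order of a millisecond, so incremental recomputation would be
complexity without benefit.

## The EHR condensation layer

Raw EHR tables are too slow to scan interactively, so a batch step
condenses them into a staging store that the advisory queries per patient:

* **Comorbidity bitflags.** Each comorbidity is defined by a set of ICD9
  prefixes in an editable YAML map; a dotted code matches a prefix when it
  equals it or extends it at a dot boundary (`311` matches `311.0`, not
  `3110`). The flag order in the map fixes each comorbidity's bit in a
  packed integer. The shipped map (heart disease, depression, diabetes,
  renal disease, seizure disorder, glaucoma) is clinically plausible
  configuration, not a validated code set — deployments are expected to
  edit it.
* **Five-year medication history.** A taxonomy order contributes when its
  active span overlaps the closed interval `[as_of - 5 years, as_of]`; an
  order ending exactly five years before the as-of date is included, one
  day earlier is not. The boundary is pinned by a dedicated test because
  "within the past five years" is exactly the kind of requirement that
  silently drifts.

Staging is a cache, never a semantic change: the test suite rebuilds a
seeded 1,000-patient cohort and checks every staged answer against a
direct scan of the full tables. Rebuilding from identical inputs is
byte-identical (the store's build date defaults to the as-of date rather
than wall-clock time), and a store older than 36 hours logs a staleness
warning when queried, mirroring a nightly-rebuild design without a
scheduler.

"Current" medications are computed live, not staged: status `active`,
started on or before the as-of date, open-ended or ending on/after it.
A discontinued order is never current even if its dates cover the day.
Drug names are normalised (lowercase, whitespace collapsed, salt suffixes
like "HCl" stripped — the suffix list is config) before matching the
taxonomy.

`facts_from_ehr()` publishes `<drug>_tx` and `<comorbidity>_hx` booleans
with provenance `extracted`, every other declared input `FALSE`. A
published name colliding with a KB-derived variable is refused outright:
the fact namespace and the rule namespace must not overlap.

## Treatment lines and the scope warning

The drug taxonomy assigns each drug a class and a line (1: TCA, SNRI,
gabapentinoid; 2: opioids, tramadol; 3: carbamazepine, lamotrigine,
topiramate, valproic acid, bupropion, citalopram, paroxetine).
`classify_regimen()` flags which lines are present among current
medications. The advisory covers first-line management only, but patients
legitimately receive second- or third-line drugs for other indications, so
the report does not suppress itself — it prepends a fixed explanatory
scope note whenever line 2 or 3 is present, and omits it otherwise. The
invariant *scope note present iff an advanced-line drug is current* is
asserted in the acceptance tests.

## The report

`assemble_report()` is a pure function from demographics, facts, regimen
and evaluation result to a sectioned document: header with comorbidity
checkboxes (each labelled `extracted` or `override`), current medications
with dose and a side-effect note key, past medications (staged history
minus current drugs), the ordered recommendations, one outline panel per
drug-class or auxiliary category (the layout config maps locations to
panels; a placement to an unmapped location is refused by name), and a
link registry of symbolic targets. Three renderings — JSON, a static HTML
page whose outline panels are `<details>` elements, and plain text —
carry identical comment texts in identical order, byte for byte, and
contain no timestamps, so rendering is deterministic.

## The synthetic cohort generator

The generator emulates only the statistical structure the extractor
consumes: independent per-patient comorbidity draws at configurable
prevalences (defaults: heart disease 0.25, depression 0.30, diabetes 0.25,
renal disease 0.10, seizure disorder 0.05, glaucoma 0.08 — plausible for
an older, largely male primary-care population with chronic pain), and
exactly one medication scenario per patient (`naive` 0.25,
`first_line_only` 0.35, `first_plus_second` 0.15, `third_line` 0.10,
`past_only` 0.15). Diagnosis codes are drawn from the comorbidity map's
prefixes, extended with random decimals, plus roughly 20% decoy codes
mapping to no comorbidity so the prefix-match negative path is always
exercised. Each patient's records derive from a counter-based sub-seed of
the cohort seed, so generation is reproducible bit for bit and
insensitive to insertion order.

What the generator does **not** emulate: correlated comorbidities,
longitudinal disease trajectories, dosage titration, coding noise
(typos, ICD10, local code extensions) or free-text orders. Passing tests
therefore demonstrate the *mechanics* — extraction, staging consistency,
routing, rendering — not clinical validity of the shipped comorbidity map
or taxonomy on real charts.

Hand-authored `demo_patient()` fixtures cover the worked examples: the
amitriptyline-plus-depression patient that exercises both comment routes,
and the gabapentin-plus-oxycodone patient that triggers the scope note.

## Numerical and design choices

* Rule targets default to `FALSE` before the pass, so a rule that does not
  fire yields a definite false, never an unbound variable; only variables
  that no rule can assign and no config declares raise evaluation errors.
* `order` ties: stable by declaration order. Duplicate placement of one
  comment in one location keeps the earliest sort position.
* Identifiers are case-sensitive `[A-Za-z_][A-Za-z0-9_]*`.
* Year arithmetic for the lookback is calendar-aware; February 29 anchors
  clamp to February 28.
* Problem sizes in the verification suite: round-trip and equivalence
  properties use generated KBs of up to 20 rules and 20 comments; the
  exhaustive oracle-equivalence check runs 200 KBs with 1–12 inputs
  (weighted towards small input counts so exhaustive enumeration stays
  cheap) over all `2^n` assignments; staging consistency uses a
  1,000-patient cohort. These sizes comfortably bracket the shipped demo
  KB (5 rules, 7 comments, 12 inputs).

## Limitations

* The engine evaluates booleans only; age- or dose-conditioned logic must
  be pre-computed into boolean facts by the extraction layer.
* The shipped comorbidity map and taxonomy are demonstration
  configuration; clinical deployment requires locally validated code sets
  and formulary content.
* The demo KB's comment texts are placeholders except where noted; the
  package ships machinery, not a vetted clinical knowledge base.
* No EHR interface adapters (HL7/FHIR, RPC) are included; the extraction
  layer consumes flat tables.
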