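# Demonstration knowledge base for first-line neuropathic-pain
# pharmacotherapy.  Comment texts marked [placeholder] are illustrative
# stand-ins for full clinical guidance, which is deployment content.

# ---- derivation rules ------------------------------------------------

if (amitriptyline_tx || nortriptyline_tx) tca_tx = true;
if (duloxetine_tx || venlafaxine_tx) snri_tx = true;
if (gabapentin_tx || pregabalin_tx) gabapentinoid_tx = true;
if (tca_tx || snri_tx || gabapentinoid_tx) first_line_tx = true;
if (heart_disease_hx || glaucoma_hx) tca_caution = true;

# ---- conditional comments --------------------------------------------

Comment TCA_depression {
  Condition: tca_tx & depression_hx; Where: Recommendations (order: 7);
  Condition: depression_hx; Where: TCA_comments (order: 5);
  Text: "The presence of depression is not required for the analgesic effects of TCAs, although they may be particularly useful in patients with inadequately treated depression."
}

Comment TCA_cardiac {
  Condition: tca_tx & heart_disease_hx; Where: Recommendations (order: 3);
  Condition: heart_disease_hx; Where: TCA_comments (order: 2);
  Text: "[placeholder] TCAs can affect cardiac conduction; use caution and consider an alternative first-line agent in patients with heart disease."
}

Comment TCA_glaucoma {
  Condition: tca_tx & glaucoma_hx; Where: Recommendations (order: 4);
  Condition: glaucoma_hx; Where: TCA_comments (order: 3);
  Text: "[placeholder] Anticholinergic effects of TCAs may worsen narrow-angle glaucoma."
}

Comment Gabapentinoid_renal {
  Condition: gabapentinoid_tx & renal_disease_hx; Where: Recommendations (order: 5);
  Condition: renal_disease_hx; Where: Gabapentin_comments (order: 1);
  Text: "[placeholder] Gabapentin and pregabalin are renally cleared; reduce dose in chronic kidney disease."
}

Comment SNRI_option {
  Condition: !snri_tx & depression_hx & !tca_caution; Where: SNRI_comments (order: 1);
  Condition: !snri_tx & depression_hx & !tca_caution; Where: Recommendations (order: 8);
  Text: "[placeholder] An SNRI (duloxetine or venlafaxine) may address both neuropathic pain and depression in this patient."
}

Comment Untreated_first_line {
  Condition: !first_line_tx; Where: Recommendations (order: 1);
  Text: "[placeholder] No current first-line neuropathic-pain medication found; consider a TCA, SNRI, or gabapentinoid if NP treatment is indicated."
}

Comment Neuro_consult_workup {
  Condition: first_line_tx; Where: Before_Requesting_a_Neurology_Consultation (order: 1);
  Text: "[placeholder] Before requesting a neurology consultation, document the first-line agents tried, maximum tolerated doses, and treatment durations."
}
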