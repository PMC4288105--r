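# Declared inputs (published by the extraction layer) and the location
# registry for the demonstration knowledge base.
inputs:
  # current first-line medication facts
  - amitriptyline_tx
  - nortriptyline_tx
  - duloxetine_tx
  - venlafaxine_tx
  - gabapentin_tx
  - pregabalin_tx
  # comorbidity facts (chart-extracted checkboxes)
  - heart_disease_hx
  - depression_hx
  - diabetes_hx
  - renal_disease_hx
  - seizure_disorder_hx
  - glaucoma_hx
locations:
  - Recommendations
  - TCA_comments
  - SNRI_comments
  - Gabapentin_comments
  - Before_Requesting_a_Neurology_Consultation
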