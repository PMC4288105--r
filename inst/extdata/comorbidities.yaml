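# Comorbidity -> ICD9 prefix sets.  Order fixes each comorbidity's bit
# position in staging records.  Prefixes are clinically plausible,
# editable configuration; they must not overlap across comorbidities.
heart_disease:
  - "410"   # acute myocardial infarction
  - "411"
  - "412"
  - "413"   # angina
  - "414"   # chronic ischemic heart disease
  - "428"   # heart failure
depression:
  - "296.2" # major depressive disorder, single episode
  - "296.3" # recurrent
  - "300.4" # dysthymia
  - "311"   # depressive disorder NEC
diabetes:
  - "250"
renal_disease:
  - "585"   # chronic kidney disease
seizure_disorder:
  - "345"   # epilepsy
glaucoma:
  - "365"
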