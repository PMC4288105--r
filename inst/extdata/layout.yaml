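# How knowledge-base locations map onto report sections: one location
# feeds Comments/Recommendations; each remaining location fills one
# expandable outline category (the hover boxes of the screen design).
recommendations: Recommendations
outline:
  TCA: TCA_comments
  SNRI: SNRI_comments
  Gabapentin: Gabapentin_comments
  Before_Requesting_a_Neurology_Consultation: Before_Requesting_a_Neurology_Consultation
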