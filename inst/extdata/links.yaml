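# Report footer links: label -> symbolic target key.  The static pages
# themselves are deployment assets resolved outside the package.
"Diagnosing neuropathic pain": np_diagnosis
"Pregnancy and lactation risk for NP medications": np_pregnancy_lactation
"Nonformulary drug request steps": nonformulary_steps
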