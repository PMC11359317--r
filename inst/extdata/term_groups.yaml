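# Composite event groups used when screening CAR T-cell products: each label
# pools the listed preferred terms into one event before counting. Members
# must be disjoint across groups; users may extend this file.
Tremor:
  members:
    - Tremor
    - Intention tremor
    - Dystonic tremor
    - Resting tremor
    - Essential tremor
    - Action tremor
    - Postural tremor
  provenance: pooled tremor variants
Facial paralysis:
  members:
    - Facial paralysis
    - Facial paresis
  provenance: pooled facial palsy terms
Cytokine release syndrome:
  members:
    - Cytokine release syndrome
    - Cytokine storm
  provenance: pooled CRS terms
HLH:
  members:
    - Haemophagocytic lymphohistiocytosis
    - Immune effector cell-associated HLH-like syndrome
  provenance: pooled haemophagocytic syndromes
Graft versus host disease:
  members:
    - Graft versus host disease
    - Acute graft versus host disease
    - Chronic graft versus host disease
    - Graft versus host disease in liver
    - Graft versus host disease in skin
  provenance: pooled GvHD terms
Respiratory failure:
  members:
    - Respiratory failure
    - Acute respiratory failure
  provenance: pooled respiratory failure terms
Pleural effusion:
  members:
    - Pleural effusion
    - Malignant pleural effusion
  provenance: pooled pleural effusion terms
Tachycardia:
  members:
    - Tachycardia
    - Sinus tachycardia
    - Supraventricular tachycardia
    - Ventricular tachycardia
  provenance: pooled tachycardia variants
Hypotension:
  members:
    - Hypotension
    - Capillary leak syndrome
    - Orthostatic hypotension
  provenance: pooled hypotensive events
Shock:
  members:
    - Shock
    - Haemorrhagic shock
    - Distributive shock
    - Hypovolaemic shock
    - Neurogenic shock
  provenance: pooled shock states
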