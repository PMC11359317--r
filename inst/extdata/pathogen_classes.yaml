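# Illustrative, synthetic pathogen-type classes for infection preferred
# terms. The licensed MedDRA hierarchy (HLGT level) cannot ship with the
# package, so these explicit PT lists stand in for it; edit or replace them
# with lists derived from a licensed dictionary for production use.
bacterial:
  - Bacterial infection
  - Bacterial sepsis
  - Sepsis
  - Pneumonia bacterial
  - Clostridium difficile infection
  - Staphylococcal infection
  - Escherichia infection
fungal:
  - Fungal infection
  - Fungal sepsis
  - Candida infection
  - Aspergillus infection
  - Pneumocystis jirovecii pneumonia
viral:
  - Viral infection
  - Cytomegalovirus infection
  - Herpes zoster
  - Epstein-Barr virus infection
  - COVID-19
  - Influenza
  - Respiratory syncytial virus infection
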