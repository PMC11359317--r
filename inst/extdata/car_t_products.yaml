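# DRUGNAME / PROD_AI synonyms identifying the six FDA-approved CAR T-cell
# products (non-proprietary and brand names). Matching is case-insensitive
# and whitespace-normalized; extend with spelling variants as needed.
Tisa-cel:
  - tisagenlecleucel
  - Kymriah
Axi-cel:
  - axicabtagene ciloleucel
  - Yescarta
Brexu-cel:
  - brexucabtagene autoleucel
  - Tecartus
Liso-cel:
  - lisocabtagene maraleucel
  - Breyanzi
Ide-cel:
  - idecabtagene vicleucel
  - Abecma
Cilta-cel:
  - ciltacabtagene autoleucel
  - Carvykti
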