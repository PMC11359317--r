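country,region
US,North America
CA,North America
MX,North America
GB,Europe
FR,Europe
DE,Europe
IT,Europe
ES,Europe
NL,Europe
BE,Europe
SE,Europe
NO,Europe
DK,Europe
FI,Europe
CH,Europe
AT,Europe
PT,Europe
IE,Europe
PL,Europe
CZ,Europe
GR,Europe
JP,Asia
CN,Asia
KR,Asia
IN,Asia
TW,Asia
SG,Asia
TH,Asia
MY,Asia
IL,Asia
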