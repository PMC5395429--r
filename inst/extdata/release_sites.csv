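acronym,lon,lat,basin
OTH,19.935636,39.793289,adriatic_ionian
KAP,19.324967,40.392800,adriatic_ionian
BOK,18.569633,42.387533,adriatic_ionian
KOR,15.281483,43.792250,adriatic_ionian
TRE,15.523950,42.138583,adriatic_ionian
TOG,17.800050,40.716650,adriatic_ionian
OTR,18.519217,40.109233,adriatic_ionian
POC,17.917950,40.195250,adriatic_ionian
FRN,3.1374160,42.482290,western_med
TUN,10.967000,37.050440,western_med
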