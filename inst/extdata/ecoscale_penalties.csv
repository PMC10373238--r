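"method","item","points"
"cls","ethanol (>10 mL; flammable)",8
"cls","acetonitrile (plasma precipitation)",6
"cls","waste (>10 mL; no treatment)",5
"cls","energy (spectrophotometer + centrifuge)",2
"pcr","ethanol (>10 mL; flammable)",8
"pcr","acetonitrile (plasma precipitation)",6
"pcr","waste (>10 mL; no treatment)",4
"pcr","energy (spectrophotometer + centrifuge)",1
"pls","ethanol (>10 mL; flammable)",8
"pls","acetonitrile (plasma precipitation)",6
"pls","waste (>10 mL; no treatment)",6
"pls","energy (spectrophotometer + centrifuge)",2
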