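statin,ddd_mg
atorvastatin,20
fluvastatin,60
pravastatin,30
rosuvastatin,10
simvastatin,30
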