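field,mean,sd
age,29.3,6.5
body_mass,81.5,2.0
height,178.6,0.9
bmi,25.7,1.4
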