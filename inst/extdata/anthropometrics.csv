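group,n,age_mean,age_sd,body_mass_mean,body_mass_sd,height_mean,height_sd,bmi_mean,bmi_sd
missile-frigate,74,29.8,4.2,80.4,4.1,177.9,3.5,25.4,1.6
sailing-ship,30,21.6,2.8,79.5,13.8,179.3,6.7,24.8,1.4
maritime-unit,89,37.6,3.6,84.1,9.8,179.7,6.3,26.3,1.2
kashubian-division,21,28.4,2.1,82.1,7.8,177.7,6.3,26.2,1.4
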