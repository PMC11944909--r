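ship,provenance,energy_kcal,energy_sd,protein_g,protein_sd,fat_g,fat_sd,carb_g,carb_sd
missile-frigate,planned,4430.9,322.6,158.3,17.4,201.0,34.6,497.2,53.3
missile-frigate,served,4120.0,300.8,149.3,17.9,147.4,23.5,547.5,53.3
sailing-ship,planned,4234.7,419.6,163.0,14.7,167.5,28.6,518.7,64.2
sailing-ship,served,3520.9,365.0,108.2,13.9,108.7,21.3,527.5,54.2
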