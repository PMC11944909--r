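table,ship,setting,body_mass_kg,printed_total_kcal
frigate_sea,missile-frigate,at-sea,80.4,3874
sailing_sea,sailing-ship,at-sea,79.5,4031
frigate_port,missile-frigate,in-port,80.4,3648
sailing_port,sailing-ship,in-port,79.5,3380
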