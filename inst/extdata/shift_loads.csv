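unit,metric,mean,sd,median,min,max
maritime-unit,recording_time_h,15.6,6.1,11.7,7.2,23.3
maritime-unit,kcal_per_h,142,50,138,61,230
maritime-unit,kcal_per_min,2.36,0.83,2.30,1.02,3.84
maritime-unit,kcal_per_h_per_kg,2.13,0.94,1.92,0.67,3.89
maritime-unit,kcal_per_min_per_kg,0.036,0.016,0.032,0.011,0.065
maritime-unit,kcal_measured,2100,959,1661,954,4193
maritime-unit,pulse_max,149,32,140,107,220
maritime-unit,pulse_min,53,7,53,42,68
maritime-unit,pulse_mean,82,11,78,69,102
maritime-unit,kcal_per_12h,1703,599,1657,735,2762
kashubian-division,recording_time_h,25.3,0.2,25.3,25.2,25.6
kashubian-division,kcal_per_h,98,39,73,69,153
kashubian-division,kcal_per_min,1.64,0.64,1.22,1.15,2.54
kashubian-division,kcal_per_h_per_kg,1.35,0.66,0.94,0.84,2.28
kashubian-division,kcal_per_min_per_kg,0.023,0.011,0.016,0.014,0.038
kashubian-division,kcal_measured,2482,960,1868,1739,3838
kashubian-division,pulse_max,146,18,151,122,166
kashubian-division,pulse_min,55,9,61,43,62
kashubian-division,pulse_mean,77,6,79,68,83
kashubian-division,kcal_per_12h,1178,462,876,826,1830
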