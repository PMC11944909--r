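start,end,activity,rate_kcal_min_kg,printed_kcal
03:15,03:50,Night patrol,0.0433,121.8
03:50,04:00,Night watch briefing,0.0310,24.9
04:00,06:00,Change of sea watch,0.0310,299.1
06:00,06:10,Wake up and preparation for morning exercises,0.0475,38.2
06:10,06:30,Morning exercises,0.0706,113.5
06:30,06:50,Morning wash up,0.0595,95.7
06:50,07:20,Cleaning the ship,0.0425,102.5
07:20,07:50,Breakfast,0.0412,99.4
07:50,08:00,New watch briefing,0.0310,24.9
08:00,11:30,Training and ship service,0.0381,643.3
11:30,12:00,Preparation for lunch,0.0475,114.6
12:00,12:30,Lunch,0.0412,99.4
12:30,14:00,Break after lunch,0.0202,146.2
14:00,16:00,Training and ship service,0.0381,367.6
16:00,16:20,1st dinner,0.0412,66.2
16:20,16:30,Briefing and change of watch,0.0310,24.9
16:30,17:50,Time at the ship commander's disposal,0.0214,137.6
17:50,18:15,Briefing and change of watch,0.0310,62.3
18:15,19:30,Auxiliary work in the ship's kitchen,0.0614,370.2
19:30,20:00,Free time,0.0360,86.8
20:00,20:20,2nd dinner,0.0412,66.2
20:20,20:30,Watch briefing,0.0310,24.9
20:30,20:45,Change of sea watch,0.0276,33.3
20:45,21:30,Evening patrol,0.0433,156.6
21:30,21:50,Evening toilet,0.0595,95.7
21:50,22:00,Night watch briefing,0.0310,24.9
22:00,22:15,Change of sea watch,0.0276,33.3
22:15,03:15,Sleep,0.0166,400.4
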