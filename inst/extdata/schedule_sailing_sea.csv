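start,end,activity,rate_kcal_min_kg,printed_kcal
03:15,03:50,Night patrol,0.0433,120.5
03:50,04:00,Night watch briefing,0.0310,24.6
04:00,06:00,Change of sea watch,0.0310,295.7
06:00,06:10,Wake up and preparation for morning exercises,0.0475,37.8
06:10,06:30,Morning exercises,0.0706,112.2
06:30,06:50,Morning wash up,0.0595,94.6
06:50,07:20,Cleaning the ship,0.0425,101.4
07:20,07:50,Breakfast,0.0412,98.3
07:50,08:00,New watch briefing,0.0310,24.6
08:00,11:30,Training and ship service,0.0456,761.3
11:30,12:00,Preparation for lunch,0.0475,114.0
12:00,12:30,Lunch,0.0412,98.3
12:30,14:00,Break after lunch,0.0202,144.5
14:00,16:00,Training and ship service,0.0456,435.0
16:00,16:20,1st dinner,0.0412,65.5
16:20,16:30,Briefing and change of watch,0.0310,24.6
16:30,17:50,Time at the ship commander's disposal,0.0214,136.1
17:50,18:15,Briefing and change of watch,0.0310,61.6
18:15,19:30,Auxiliary work in the ship's kitchen,0.0614,368.4
19:30,20:00,Free time,0.0360,85.8
20:00,20:20,2nd dinner,0.0412,65.5
20:20,20:30,Watch briefing,0.0310,24.6
20:30,20:45,Change of sea watch,0.0276,32.9
20:45,21:30,Evening patrol,0.0433,154.9
21:30,21:50,Evening toilet,0.0595,94.6
21:50,22:00,Night watch briefing,0.0310,24.6
22:00,22:15,Change of sea watch,0.0276,37.0
22:15,03:15,Sleep,0.0166,237.5
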