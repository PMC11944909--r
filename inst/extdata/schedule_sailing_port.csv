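start,end,activity,rate_kcal_min_kg,printed_kcal
06:00,06:10,Wake up and preparation for morning exercises,0.0475,37.8
06:10,06:30,Morning exercises,0.0706,112.2
06:30,07:00,Morning wash up,0.0595,141.9
07:00,07:20,Breakfast,0.0412,65.5
07:20,07:40,Cleaning the ship,0.0624,99.2
07:40,07:50,New watch briefing,0.0310,24.6
07:50,08:00,Raising the flag,0.0310,24.6
08:00,08:35,Overview and rotated mechanisms,0.1199,333.6
08:35,12:15,Activities on the ship,0.0456,797.5
12:15,13:15,Lunch break,0.0412,196.5
13:15,15:00,Scheduled classes,0.0456,380.6
15:00,15:20,Roll call,0.0310,49.3
15:20,16:00,Cleaning the ship,0.0425,135.2
16:00,18:00,Free time,0.0214,204.2
18:00,18:30,Dinner,0.0341,98.3
18:30,21:00,Free time,0.0214,255.2
21:00,21:30,Cleaning the ship,0.0624,148.8
21:30,22:00,Evening toilet,0.0595,141.9
22:00,06:00,Sleep,0.0166,633.5
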