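start,end,activity,rate_kcal_min_kg,printed_kcal
06:00,06:10,Wake up and preparation for morning exercises,0.0475,38.2
06:10,06:30,Morning exercises,0.0706,113.5
06:30,07:00,Morning wash up,0.0595,143.5
07:00,07:20,Breakfast,0.0412,66.2
07:20,07:40,Cleaning the ship,0.0624,100.3
07:40,07:50,New watch briefing,0.0310,24.9
07:50,08:00,Raising the flag,0.0310,24.9
08:00,08:35,Overview and rotated mechanisms,0.0433,121.8
08:35,12:15,Activities on the ship,0.0433,765.9
12:15,13:15,Lunch break,0.0412,198.7
13:15,15:00,Scheduled classes,0.0433,365.5
15:00,15:20,Roll call,0.0310,49.8
15:20,16:00,Cleaning the ship,0.0425,136.7
16:00,18:00,Free time,0.0214,206.5
18:00,18:30,Dinner,0.0412,99.4
18:30,21:00,Free time,0.0214,258.1
21:00,21:30,Cleaning the ship,0.0624,150.5
21:30,22:00,Evening toilet,0.0595,143.5
22:00,06:00,Sleep,0.0166,640.6
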