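factor,level,n_runs,sn,mean
socket_arrangement,deflection,9,14.366,0.2621
socket_arrangement,non-deflection,9,18.508,0.2407
roller_speed,50,6,18.627,0.1389
roller_speed,150,6,22.379,0.2102
roller_speed,250,6,8.260,0.4050
motor_speed,50,6,7.636,0.4423
motor_speed,150,6,21.201,0.1695
motor_speed,250,6,20.430,0.1424
box_inclination,20,6,15.423,0.2622
box_inclination,30,6,14.550,0.2539
box_inclination,40,6,19.294,0.2381
chute_inclination,60,6,18.921,0.2149
chute_inclination,70,6,15.649,0.2870
chute_inclination,80,6,14.696,0.2523
belt_type,1,6,12.339,0.2765
belt_type,2,6,17.509,0.2491
belt_type,3,6,19.418,0.2286
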