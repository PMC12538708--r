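run,socket_arrangement,roller_speed,motor_speed,box_inclination,chute_inclination,belt_type
1,deflection,50,50,20,60,1
2,deflection,50,150,30,70,2
3,deflection,50,250,40,80,3
4,deflection,150,50,20,70,2
5,deflection,150,150,30,80,3
6,deflection,150,250,40,60,1
7,deflection,250,50,30,60,3
8,deflection,250,150,40,70,1
9,deflection,250,250,20,80,2
10,non-deflection,50,50,40,80,2
11,non-deflection,50,150,20,60,3
12,non-deflection,50,250,30,70,1
13,non-deflection,150,50,30,80,1
14,non-deflection,150,150,40,60,2
15,non-deflection,150,250,20,70,3
16,non-deflection,250,50,40,70,3
17,non-deflection,250,150,20,80,1
18,non-deflection,250,250,30,60,2
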