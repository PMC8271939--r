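ID,Age,Sex,Height,InitialBW_DEH,PctBWLost,InitialBW_HYD,BMI,PFA1,PFA2,PARQ,VO2max
1,23,M,182,85.60,1.52,88.50,25.8,11,9,9,51.7
2,25,M,195,98.10,2.14,98.40,25.3,11,10,7,51.4
3,27,F,165,66.10,1.21,65.00,23.8,11,9,7,51.9
4,27,M,172,66.40,1.58,66.30,22.9,12,9,7,54.1
5,23,M,182,70.45,2.20,70.60,21.7,13,11,8,57.3
6,19,M,163,70.85,1.98,70.50,26.6,11,10,7,50.4
7,27,F,178,65.95,2.43,65.00,20.8,11,10,7,48.1
8,25,M,165,76.50,2.09,76.15,25.5,11,11,9,53.4
9,42,M,195,76.80,2.28,75.75,22.1,11,11,8,55.5
10,24,F,175,75.80,2.31,75.65,24.4,10,8,7,42.9
11,27,F,155,59.45,1.93,59.35,25.3,9,9,7,42.2
12,23,F,167,66.50,2.03,67.50,24.2,11,10,7,45.3
13,28,F,170,59.00,2.03,59.35,20.8,12,12,8,51.0
14,38,F,160,58.55,2.04,57.60,22.7,9,7,7,42.8
15,18,M,180,75.20,2.53,75.10,24.0,11,9,7,51.8
16,30,F,170,59.95,1.83,59.25,20.4,9,9,7,46.2
17,26,M,178,67.35,2.15,65.95,20.8,11,9,7,54.4
18,22,M,163,66.75,1.95,68.25,24.9,12,11,8,53.9
19,30,F,170,67.10,2.01,67.10,23.8,11,9,7,44.9
20,24,F,170,59.70,2.09,59.80,19.6,11,11,8,50.5
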