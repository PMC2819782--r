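pct,observed,expected,rr_published,rr_rank_published,income,income_rank_published
Barking and Dagenham,9800,9147,1.071,25,5.3,2
Barnet,20161,19287,1.045,21,7.6,25
Bexley,13973,14778,0.946,12,6.7,14
Brent,14040,13542,1.037,20,6.6,10
Bromley,19466,20883,0.932,11,7.5,23
Camden,9430,9389,1.004,15,7.3,21
City and Hackney,9030,8746,1.033,19,5.5,4
Croydon,17519,18868,0.928,9,6.8,15
Ealing,18410,15228,1.209,29,7.3,22
Enfield,14839,16232,0.914,5,6.6,11
Greenwich,12419,11464,1.083,26,5.8,5
Hammersmith and Fulham,7022,7609,0.923,7,7.8,27
Haringey,9318,9360,0.996,14,6.6,12
Harrow,13680,12949,1.056,22,7.7,26
Havering,16650,16538,1.007,16,6.9,16
Hillingdon,13929,14408,0.967,13,7.2,19
Hounslow,8127,7663,1.061,24,6.5,9
Islington,13929,14408,0.967,13,7.2,19
Kensington and Chelsea,6953,9506,0.731,1,8.0,28
Kingston,8573,8485,1.010,17,8.1,29
Lambeth,9768,10499,0.930,10,6.6,13
Lewisham,12027,11348,1.060,23,6.1,8
Newham,12495,9433,1.325,31,4.8,1
Redbridge,14488,14223,1.019,18,6.9,17
Richmond and Twickenham,7802,10312,0.757,2,9.0,31
Southwark,10233,11168,0.916,6,6.0,6
Sutton and Merton,19303,21385,0.903,4,7.6,24
Tower Hamlets,9724,7523,1.293,30,5.4,3
Waltham Forest,11955,10640,1.124,27,6.0,7
Wandsworth,10904,11763,0.927,8,8.4,30
Westminster,9921,11097,0.894,3,7.1,18
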