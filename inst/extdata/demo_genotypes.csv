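individual_id,population_id,du_id,behaviour,x,y,loc01_a1,loc01_a2,loc02_a1,loc02_a2,loc03_a1,loc03_a2,loc04_a1,loc04_a2,loc05_a1,loc05_a2
ind_001,pop1,DU_A,migratory,9186.08729166236,5301.56490323183,2,2,2,2,1,5,5,6,1,3
ind_002,pop1,DU_A,unclassified,11296.2912384069,4636.8807651336,2,2,2,2,3,7,5,4,1,1
ind_003,pop1,DU_A,migratory,11999,5811.4805667649,2,5,5,1,4,8,4,2,1,1
ind_004,pop1,DU_A,migratory,11999,4371.1530281025,2,2,2,6,8,4,5,2,5,5
ind_005,pop1,DU_A,migratory,10444.6370113019,6167.98915627043,2,5,1,2,7,5,4,5,2,1
ind_006,pop1,DU_A,unclassified,10958.440639816,4456.28130871573,2,1,5,6,7,3,5,6,1,1
ind_007,pop1,DU_A,unclassified,7671.97548395043,4937.42337670546,2,2,6,5,8,4,5,5,4,5
ind_008,pop1,DU_A,unclassified,10098.8703671091,6450.0470401054,2,2,5,6,2,4,5,1,3,1
ind_009,pop2,DU_A,unclassified,2742.87410930827,8815.83032883757,2,1,5,2,8,8,5,5,5,3
ind_010,pop2,DU_A,migratory,4289.46429040019,7787.23998921546,2,2,6,6,3,7,5,5,2,3
ind_011,pop2,DU_A,migratory,4465.71760621812,7954.08784736001,4,2,2,3,3,8,5,6,3,1
ind_012,pop2,DU_A,migratory,4228.80092694652,10521.9745554012,2,5,2,2,3,7,5,1,1,4
ind_013,pop2,DU_A,migratory,4606.0300021634,9775.22599478385,3,2,5,5,3,7,5,5,1,5
ind_014,pop2,DU_A,migratory,3589.87101636274,10782.7500932623,2,6,5,2,5,3,5,1,1,1
ind_015,pop2,DU_A,migratory,2780.95282351954,9641.03980306776,2,2,5,3,7,7,2,2,1,1
ind_016,pop2,DU_A,migratory,4064.99542651428,11194.2387277905,6,2,2,6,3,7,1,5,4,1
ind_017,pop3,DU_B,migratory,5471.88563206167,1690.19197696635,6,6,5,3,1,3,5,8,1,3
ind_018,pop3,DU_B,migratory,702.270408178074,3359.15980556287,5,6,2,6,4,7,8,1,1,3
ind_019,pop3,DU_B,unclassified,5692.49010646033,1888.63731519883,2,2,6,5,7,8,8,2,2,2
ind_020,pop3,DU_B,unclassified,6147.62311647148,3434.03231163701,2,2,3,5,1,8,5,1,1,5
ind_021,pop3,DU_B,migratory,4799.86117873366,2959.13072995379,6,2,2,3,7,7,6,4,1,1
ind_022,pop3,DU_B,migratory,5159.37899103074,2970.85644441843,5,4,6,3,8,8,4,1,4,4
ind_023,pop3,DU_B,migratory,2113.08535513298,1600.99581158411,2,2,6,3,6,8,6,5,5,5
ind_024,pop3,DU_B,migratory,5991.53307806453,1,2,2,5,3,1,1,1,8,1,2
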