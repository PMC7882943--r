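year,distance_km,birds_within_300m,flying_within_300m,days,birds_total,cells_with_birds
2013,2232,43,43,16,66,42
2014,2621,130,80,14,168,61
2015,2414,73,64,18,62,33
2016,1896,36,33,16,84,34
2017,3203,30,26,36,13,9
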