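survey,stations,mean_neighbour_dist_km,mean_neighbour_dist_sd_km,tn_total,tn_20station
2003,33,1.17,0.77,2898,2345
2004,84,0.80,0.69,4858,2068
2005,30,1.98,0.54,2880,2682
2007,31,1.77,0.51,3466,2172
2008,50,1.29,0.31,3159,1425
2011,19,1.98,0.54,1607,1607
2012,20,1.98,0.54,1800,1800
2013,30,1.22,0.95,7166,6039
2014,23,1.57,0.84,3341,3223
2015,77,0.50,0.59,6828,2473
2016,72,0.46,0.69,8568,2122
2017,48,0.67,0.78,8293,3252
1314,20,1.98,0.54,NA,9262
1617,55,0.14,0.12,11486,NA
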