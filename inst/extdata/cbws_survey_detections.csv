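survey,scope,males_min,males_max,females_min,females_max,unknown_min,unknown_max,total_min,total_max,events,det_per_100tn
2003,all,3,4,3,3,2,4,8,11,19,0.66
2003,grid20,2,2,2,2,2,3,6,7,12,0.51
2004,all,8,9,3,3,5,10,16,22,30,0.58
2004,grid20,6,7,2,2,2,5,10,14,18,0.87
2005,all,2,3,1,1,1,1,4,5,12,0.42
2005,grid20,2,3,1,1,1,1,4,5,12,0.45
2007,all,9,10,5,5,6,8,20,23,36,1.04
2007,grid20,9,10,4,4,6,7,19,21,31,1.43
2008,all,10,11,4,4,2,3,16,18,29,0.89
2008,grid20,7,7,3,3,1,2,11,12,21,1.47
2011,all,5,5,0,0,5,5,10,10,13,0.81
2011,grid20,5,5,0,0,5,5,10,10,13,0.81
2012,all,3,3,0,0,0,1,3,4,8,0.44
2012,grid20,3,3,0,0,0,1,3,4,8,0.44
2013,all,14,16,10,11,4,7,28,34,55,0.77
2013,grid20,14,16,10,11,4,7,28,34,55,0.91
2014,all,8,8,7,8,3,7,18,23,36,1.08
2014,grid20,8,8,7,8,3,7,18,23,36,1.12
2015,all,10,11,3,3,9,13,22,27,38,0.56
2015,grid20,7,7,1,1,6,8,14,16,19,0.77
2016,all,6,8,5,5,8,13,19,26,57,0.67
2016,grid20,0,0,0,0,3,3,3,3,3,0.14
2017,all,11,12,6,6,6,17,23,35,78,0.94
2017,grid20,7,7,2,2,4,10,13,19,24,0.74
1314,grid20,15,17,11,13,8,13,34,43,87,0.94
1617,all,7,12,7,7,8,14,22,33,97,0.95
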