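frame,time_ns,n_aggregates,avg_aggregation_number,complex_ratio,free_CM15,free_SUR,contacts_CM15,contacts_SUR
1,0,2,4,1,0,0,NA,NA
2,10,2,4,1,0,0,NA,NA
3,20,2,4,1,0,0,NA,NA
4,30,2,4,1,0,0,NA,NA
5,40,1,8,1,0,0,NA,NA
6,50,1,8,1,0,0,NA,NA
7,60,1,8,1,0,0,NA,NA
8,70,1,8,1,0,0,NA,NA
9,80,1,8,1,0,0,NA,NA
10,90,1,8,1,0,0,NA,NA
11,100,1,8,1,0,0,NA,NA
12,110,1,8,1,0,0,NA,NA
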