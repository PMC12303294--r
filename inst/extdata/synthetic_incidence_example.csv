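"cancer","gender","age_group","age_class","incidence"
"synthetic bladder","female","0-14",1,0
"synthetic bladder","female","15-39",2,0.1976
"synthetic bladder","female","40-44",3,0.7441
"synthetic bladder","female","45-49",4,1.7891
"synthetic bladder","female","50-54",5,3.3239
"synthetic bladder","female","55-59",6,5.2097
"synthetic bladder","female","60-64",7,7.6667
"synthetic bladder","female","65-69",8,11.3655
"synthetic bladder","male","0-14",1,0
"synthetic bladder","male","15-39",2,0.2892
"synthetic bladder","male","40-44",3,1.8272
"synthetic bladder","male","45-49",4,5.7911
"synthetic bladder","male","50-54",5,11.5149
"synthetic bladder","male","55-59",6,22.8288
"synthetic bladder","male","60-64",7,36.331
"synthetic bladder","male","65-69",8,50.4987
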