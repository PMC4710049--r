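sample,tissue,gene,sex,no_signal,x_eq_1,y_eq_1,mixed,x_specific,y_specific,total
E27_S44,SC,PCDH11,female,3442,470,1,0,89,0,4002
E31_S91,SC,PCDH11,female,3358,190,4,0,23,1,3576
E49_S82,SC,PCDH11,female,4793,252,18,0,34,0,5097
E33_S50,MO,PCDH11,female,13517,1479,10,6,321,0,15333
E34_S20,MO,PCDH11,female,12485,1069,0,0,192,0,13746
E33_S63,MO,PCDH11,female,16189,1042,45,1,113,0,17390
E34_S63,MO,PCDH11,female,25784,1452,85,13,151,0,27485
E32_S53,SC,PCDH11,male,4915,106,61,10,5,14,5111
E32_S84,SC,PCDH11,male,4319,257,269,45,31,18,4939
E45_S75,MO,PCDH11,male,14214,895,427,108,87,28,15759
E61_S49,MO,PCDH11,male,5944,636,78,21,122,2,6803
E41_S58,MO,PCDH11,male,6824,409,99,13,41,0,7386
E45_S50,MO,PCDH11,male,16881,1553,948,240,175,85,19882
E58_S82,MO,PCDH11,male,9437,1122,356,160,241,15,11331
E61_S72,MO,PCDH11,male,6848,373,194,17,34,6,7472
E27_S48,SC,NLGN4,female,3098,364,3,4,45,0,3514
E31_S56,SC,NLGN4,female,2955,493,3,0,94,1,3546
E49_S81,SC,NLGN4,female,4225,350,4,0,47,0,4626
E49_S82,SC,NLGN4,female,4767,297,9,1,23,0,5097
E33_S62,MO,NLGN4,female,12552,1917,20,4,284,0,14777
E34_S61,MO,NLGN4,female,22028,3586,40,25,674,5,26358
E33_S63,MO,NLGN4,female,15497,1652,49,14,177,1,17390
E34_S63,MO,NLGN4,female,24119,2871,76,33,381,5,27485
E26_S65,SC,NLGN4,male,3165,200,303,36,26,25,3755
E32_S29,SC,NLGN4,male,3917,319,447,75,25,36,4819
E32_S84,SC,NLGN4,male,4120,310,381,69,28,31,4939
E61_S39,MO,NLGN4,male,5283,379,414,58,19,47,6200
E61_S89,MO,NLGN4,male,6123,633,710,117,56,75,7714
E45_S48,MO,NLGN4,male,16555,1564,1580,295,133,144,20271
E41_S58,MO,NLGN4,male,5719,563,584,421,50,49,7386
E45_S50,MO,NLGN4,male,16356,1644,1261,391,155,75,19882
E58_S82,MO,NLGN4,male,8219,1205,1102,491,200,114,11331
E61_S72,MO,NLGN4,male,6405,273,645,68,19,62,7472
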