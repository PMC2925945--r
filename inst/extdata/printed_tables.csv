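table,model,row,count,denom,printed_pct,consistent
1,series1,male,53,73,73,TRUE
1,series1,female,20,73,27,TRUE
1,series1,noninvasive,42,73,58,TRUE
1,series1,low_grade,35,42,83,TRUE
1,series1,high_grade,7,42,17,TRUE
1,series1,invasive,31,73,42,TRUE
1,series1,tp53_low,50,73,68,TRUE
1,series1,tp53_high,23,73,32,TRUE
1,series2,male,200,264,76,TRUE
1,series2,female,64,264,24,TRUE
1,series2,noninvasive,189,264,72,TRUE
1,series2,low_grade,162,189,86,TRUE
1,series2,high_grade,27,189,14,TRUE
1,series2,invasive,75,264,28,TRUE
1,series2,tp53_low,195,264,74,TRUE
1,series2,tp53_high,69,264,26,TRUE
1,series3,male,190,245,78,TRUE
1,series3,female,55,245,22,TRUE
1,series3,noninvasive,181,245,74,TRUE
1,series3,low_grade,158,181,87,TRUE
1,series3,high_grade,23,181,13,TRUE
1,series3,invasive,64,245,26,TRUE
1,series3,tp53_low,189,244,77,TRUE
1,series3,tp53_high,55,244,23,TRUE
2,hoxb2,neg_noninv,110,118,93,TRUE
2,hoxb2,neg_inv,8,118,7,TRUE
2,hoxb2,pos_noninv,61,114,54,TRUE
2,hoxb2,pos_inv,53,114,46,TRUE
2,hoxb2,tp53low_noninv,154,180,86,TRUE
2,hoxb2,tp53low_inv,26,180,14,TRUE
2,hoxb2,tp53high_noninv,17,52,33,TRUE
2,hoxb2,tp53high_inv,35,52,67,TRUE
2,krt13,neg_noninv,91,113,80,FALSE
2,krt13,neg_inv,22,113,20,FALSE
2,krt13,pos_noninv,79,119,66,TRUE
2,krt13,pos_inv,40,119,34,TRUE
2,krt13,tp53high_noninv,16,52,31,TRUE
2,krt13,tp53high_inv,36,52,69,TRUE
2,frzb,neg_noninv,93,117,80,FALSE
2,frzb,neg_inv,24,117,20,FALSE
2,frzb,pos_noninv,84,121,69,TRUE
2,frzb,pos_inv,37,121,31,TRUE
2,frzb,tp53low_noninv,160,186,86,TRUE
2,frzb,tp53low_inv,26,186,14,TRUE
2,mutual,hoxb2_neg_noninv,104,111,94,TRUE
2,mutual,hoxb2_neg_inv,7,111,6,TRUE
2,mutual,hoxb2_pos_noninv,58,108,54,TRUE
2,mutual,hoxb2_pos_inv,50,108,46,TRUE
2,mutual,krt13_neg_noninv,86,105,82,TRUE
2,mutual,krt13_neg_inv,19,105,18,TRUE
2,mutual,krt13_pos_noninv,76,114,67,TRUE
2,mutual,krt13_pos_inv,38,114,33,TRUE
2,mutual,frzb_neg_noninv,84,107,78,FALSE
2,mutual,frzb_neg_inv,23,107,22,FALSE
2,mutual,frzb_pos_noninv,78,112,70,TRUE
2,mutual,frzb_pos_inv,34,112,30,TRUE
2,mutual,tp53low_noninv,146,172,85,TRUE
2,mutual,tp53low_inv,26,172,15,TRUE
2,mutual,tp53high_noninv,16,47,34,TRUE
2,mutual,tp53high_inv,31,47,66,TRUE
3,panel,fewer_low,125,133,94,TRUE
3,panel,fewer_high,8,133,6,TRUE
3,panel,all3_low,18,29,62,TRUE
3,panel,all3_high,11,29,38,TRUE
3,panel,tp53low_low,133,146,91,TRUE
3,panel,tp53low_high,13,146,9,TRUE
3,panel,tp53high_low,10,16,62,TRUE
3,panel,tp53high_high,6,16,38,TRUE
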