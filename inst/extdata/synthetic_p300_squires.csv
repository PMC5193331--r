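"condition","pattern","value"
0.3,"XXXXX",11.1091
0.3,"XXXYX",13.9064
0.3,"XXYXX",13.1769
0.3,"XXYYX",14.2753
0.3,"XYXXX",13.0137
0.3,"XYXYX",12.9713
0.3,"XYYXX",14.4022
0.3,"XYYYX",14.6786
0.3,"YXXXX",11.7852
0.3,"YXXYX",13.5629
0.3,"YXYXX",15.0709
0.3,"YXYYX",14.3021
0.3,"YYXXX",12.7545
0.3,"YYXYX",13.7808
0.3,"YYYXX",13.9389
0.3,"YYYYX",16.0221
0.5,"XXXXX",10.4966
0.5,"XXXYX",11.494
0.5,"XXYXX",12.0294
0.5,"XXYYX",12.4527
0.5,"XYXXX",11.9432
0.5,"XYXYX",11.2657
0.5,"XYYXX",12.5457
0.5,"XYYYX",13.0007
0.5,"YXXXX",11.2803
0.5,"YXXYX",11.8558
0.5,"YXYXX",13.2567
0.5,"YXYYX",12.2644
0.5,"YYXXX",11.5947
0.5,"YYXYX",12.3493
0.5,"YYYXX",12.7237
0.5,"YYYYX",14.1439
0.7,"XXXXX",9.7013
0.7,"XXXYX",10.5968
0.7,"XXYXX",10.3537
0.7,"XXYYX",11.4484
0.7,"XYXXX",10.4938
0.7,"XYXYX",10.1481
0.7,"XYYXX",10.8951
0.7,"XYYYX",12.3953
0.7,"YXXXX",10.2628
0.7,"YXXYX",10.324
0.7,"YXYXX",11.3728
0.7,"YXYYX",11.1675
0.7,"YYXXX",10.383
0.7,"YYXYX",11.0913
0.7,"YYYXX",10.7809
0.7,"YYYYX",13.2387
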