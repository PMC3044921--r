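item,stage,median,p30,p70,appropriateness,disagreement_index
1a,1,6.0,6,7,Appropriate,0.16
1b,1,6.5,6,8,Appropriate,0.29
2a,1,4.0,3,5,Uncertain,0.85
2b,1,8.0,7,8,Appropriate,0.13
3a,1,5.5,5,6,Appropriate,0.22
3b,1,4.5,3,6,Uncertain,0.97
4a,1,4.5,3,6,Uncertain,0.97
4b,1,5.0,4,5,Uncertain,0.32
5a,1,6.5,6,8,Appropriate,0.29
5b,1,5.0,3,6,Uncertain,0.97
6a,1,8.0,8,8,Appropriate,0.00
6b,1,4.5,3,6,Uncertain,0.97
6c,1,6.5,5,7,Appropriate,0.37
1,2,6.0,4,7,Appropriate,0.65
2,2,0.0,0,5,Inappropriate,1.09
3,2,6.0,5,6,Appropriate,0.29
4,2,4.0,2,2,Uncertain,0.96
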