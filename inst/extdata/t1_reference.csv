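system,label,t1_free,t1_free_hi,t1_complex,t1_complex_hi,percent_change
2HP-b-CD,H1'',1.40,1.54,1.39,1.52,2
2HP-b-CD,H8'',1.72,,1.73,,1
2HP-b-CD,H3'',1.23,,1.23,,0
2HP-b-CD,H6'',1.44,,1.28,,16
2HP-b-CD,H2''-H4''-H5'',1.42,,1.20,,22
2HP-b-CD,H7'',1.55,,1.55,,0
2HP-b-CD,H9'',1.19,,1.20,,1
2-6Me-b-CD,H1,1.36,1.40,1.35,1.40,1
2-6Me-b-CD,H3,1.49,,1.51,,2
2-6Me-b-CD,H5,1.41,,1.18,,23
2-6Me-b-CD,H6,1.34,,1.12,,22
2-6Me-b-CD,H2,1.36,,1.12,,24
2-6Me-b-CD,H4,1.35,,1.28,,7
2-6Me-b-CD,H6-O-Me,1.76,,1.79,,3
2-6Me-b-CD,H2b,1.51,,1.39,,12
2-6Me-b-CD,H2-O-Me,1.64,,1.62,,2
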