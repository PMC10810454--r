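code,name,area_m2,percent_exhibit
B1,Beach 1,34.10,5.49
B2,Beach 2,45.60,7.35
B3,Beach 3,15.30,2.47
BW,Bridge water,183.02,29.49
CW,Central water,200.37,32.28
HW,Holding water,41.58,6.70
I1,Island 1,8.59,1.38
I2,Island 2,20.02,3.23
I3,Island 3,21.74,3.50
NLB,Narrow land between beaches,5.29,0.85
NLW,Narrow land between water,3.54,0.57
SC,Shallow channel,41.50,6.69
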