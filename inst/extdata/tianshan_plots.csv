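plot,site,SR,PD,RPD,NRI,NTI,pd_flag,rpd_flag,nri_flag,nti_flag
BLK-1,BLK,14,0.1475,2.0631,-1.1532,-0.1697,high,none,none,none
QT-1,QT,15,0.1582,1.6598,-1.2239,-2.1374,none,none,none,low
QT-2,QT,12,0.1512,1.8133,-1.3013,1.1080,none,none,none,none
FK-1,FK,12,0.1385,1.6605,-2.3838,0.5205,none,none,low,none
FK-2,FK,10,0.1349,1.8867,-0.4110,0.0948,none,none,none,none
FK-3,FK,15,0.1617,1.5779,-0.2466,-1.8519,none,none,none,none
WLMQ-1,WLMQ,17,0.1729,1.4511,-1.4490,-0.4374,high,none,none,none
WLMQ-2,WLMQ,15,0.1664,1.6239,-0.6715,-2.0574,none,none,none,low
WLMQ-3,WLMQ,20,0.1739,1.4033,-0.8204,-0.9642,none,none,none,none
HTB-1,HTB,13,0.1741,1.3789,0.9930,-0.0286,none,none,none,none
HTB-2,HTB,19,0.1589,1.5883,-0.1015,-0.5493,none,high,none,none
HTB-3,HTB,18,0.1434,1.7704,0.7109,0.1061,none,none,none,none
MNS-1,MNS,15,0.1399,1.7793,-0.4440,-1.6448,none,none,none,none
MNS-2,MNS,20,0.1235,1.9930,0.1306,-0.6166,low,high,none,none
MNS-3,MNS,20,0.1415,1.8002,-0.9503,-0.3559,none,high,none,none
SHZ-1,SHZ,16,0.1357,1.8371,-0.2294,-1.8101,none,high,none,none
SHZ-2,SHZ,19,0.1231,2.2466,-0.0004,-0.5385,low,high,none,none
SHZ-3,SHZ,14,0.1291,1.8684,-0.5415,-3.0565,none,none,none,none
JH-1,JH,17,0.1342,1.6567,-0.3743,-1.1535,none,none,none,none
BL-1,BL,17,0.1392,1.7178,1.0860,0.4079,none,none,none,none
BL-2,BL,15,0.1347,1.570,1.5585,-0.3073,none,none,none,none
TL-1,TL,19,0.1415,1.5231,0.1369,0.9495,none,none,none,none
YM-1,YM,19,0.1379,1.5643,0.5058,1.0113,none,none,none,none
YM-2,YM,16,0.1082,1.6827,1.9020,-0.5231,low,none,none,none
CBCE-1,CBCE,11,0.1403,1.8989,-0.9553,-0.6859,none,none,none,none
TKS-1,TKS,19,0.1520,1.6792,0.4271,-0.4355,none,none,none,none
TKS-2,TKS,16,0.1408,1.5546,-1.7076,-1.8259,none,none,none,none
NLK-1,NLK,17,0.1394,1.8286,-0.9018,1.3315,none,high,none,none
NLK-2,NLK,17,0.1386,1.6159,0.0499,-0.7032,low,none,none,none
GL-1,GL,25,0.1573,1.4674,-0.6591,-1.4401,none,none,none,none
GL-2,GL,26,0.1669,1.4590,-0.3412,-0.4477,none,none,none,none
XY-1,XY,22,0.1639,1.4041,-1.5927,0.2293,none,none,none,none
XY-2,XY,26,0.1736,1.3249,-0.5089,0.6486,none,none,none,none
ZS-1,ZS,28,0.1736,1.3489,-0.8273,0.0163,none,none,none,none
ZS-2,ZS,26,0.1674,1.5277,-0.7660,-1.1037,none,none,none,none
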