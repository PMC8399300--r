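parameter,textile,domestic
C_T1,1340,415
S_T1,965,120
X_T1,375,295
S_S1,280,40
S_HT1,460,62
S_H1,100,15
S_HC1,360,47
S_IT1,225,18
S_I1,135,10
S_IC1,90,8
X_ST1,360,253
X_S1,162,113
X_SS1,198,140
X_IT1,15,42
X_I1,7,19
X_IS1,8,23
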