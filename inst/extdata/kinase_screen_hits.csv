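rank,compound,concentration,composite_z,target
1,H-9,10,-1.97,PKG and PKA
2,URMC-099,1,-1.79,"LRRK2, MLKs"
3,ARQ-092,10,-1.76,PKB/Akt
4,AZD 1208,1,-1.68,PIMs
5,Go 6983,10,-1.68,PKCs
6,AP26113,10,-1.67,ALK
7,SC-1,10,-1.63,ERK1
8,(R)-Crizotinib,1,-1.54,"c-Met, ALK"
9,Bisindolylmaleimide I,10,-1.52,PKCs
10,KW 2449,1,-1.45,"FLT3, ABL"
11,AG-825,10,-1.43,ErbB2
12,Kenpaullone,10,-1.39,"GSK3B, CDKs"
13,PP242,1,-1.39,mTOR
14,LOXO-101,1,-1.35,Trk family
15,ML-9,10,-1.30,Multikinase
16,AZ191,1,-1.30,DYRK1b
17,IKKe,1,-1.21,IKKe
18,(R)-Roscovitine,1,-1.19,CDKs
19,Sorafenib,1,-1.17,Raf-1
20,SB 202190,10,-1.16,p38 MAPK
21,NVP-AEW541,1,-1.15,IGF-1R
22,Tie2 Kinase Inhibitor,1,-1.08,Tie2
23,PF-06463922,10,-1.07,ALK
24,ARQ-092,1,-1.03,PKB/Akt
25,PF-562271,1,-1.01,FAK
26,Torin 1,1,-0.98,mTOR
27,Y-27632,1,-0.98,ROCK-1
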