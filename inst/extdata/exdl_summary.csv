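protein,donor,subunit,xm_rc_nm,rc_min,rc_max,note
FBP,Trp32,A,0.82,0.64,0.80,entirely distance-inverted
FBP,Trp32,B,0.82,0.62,0.78,entirely distance-inverted
FBP,Trp106,A,0.90,0.82,1.10,
FBP,Trp106,B,0.94,0.82,1.82,
WT P2O,Trp168,B,0.74,0.66,0.82,
WT P2O,Trp168,C,0.73,0.71,0.82,
WT P2O,Trp168,D,0.73,0.69,0.83,
T169S P2O,Trp168,A,0.71,0.68,0.79,
T169S P2O,Trp168,B,0.73,NA,NA,distance range not quoted
T169S P2O,Trp168,C,NA,0.66,0.79,linear profile; no distance-axis peak quoted
T169S P2O,Trp168,D,0.72,0.68,0.84,
MCAD,Trp166,A,0.76,0.77,1.0,
MCAD,Trp166,B,0.81,0.72,0.97,
MCAD,Trp166,C,0.74,0.75,0.95,
MCAD,Trp166,D,0.80,0.75,1.0,
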