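protein,donor,subunit,a2,b2,c2,xm_es_printed,neg_sfeg_min,neg_sfeg_max,known_mismatch,note
FBP,Trp32,A,-26.1,40.3,-13.4,0.77,0.87,1.15,FALSE,printed vertex lies below the printed -SFEG range
FBP,Trp32,B,-27.1,40,-12.7,0.82,0.78,1.15,TRUE,printed vertex matches the distance-axis peak; coefficients give 0.74
FBP,Trp106,A,-28,47.7,-18,0.90,0.72,1.10,TRUE,printed vertex matches the distance-axis peak; coefficients give 0.85
FBP,Trp106,B,-114,193,-80,0.94,0.5,0.95,TRUE,printed vertex matches the distance-axis peak; coefficients give 0.85; running text gives b2 = 194
WT P2O,Trp168,B,-15.3,56.8,-50,1.86,1.81,1.92,FALSE,running text gives a2 = -15.8; the tabulated -15.3 reproduces the printed vertex
WT P2O,Trp168,C,-13.4,50,-43.8,1.87,1.79,1.91,FALSE,
WT P2O,Trp168,D,-18.3,68.2,-60.5,1.86,1.79,1.89,FALSE,
T169S P2O,Trp168,A,-13.4,56.4,-57,2.10,1.62,1.71,FALSE,
T169S P2O,Trp168,B,-24.4,103,-1.7,2.11,1.62,1.71,FALSE,
T169S P2O,Trp168,D,-22.4,95.4,-98.8,2.13,1.61,1.71,FALSE,
MCAD,Trp166,A,-19.3,92.5,-110,2.40,2.33,2.54,FALSE,
MCAD,Trp166,B,-9.28,43.9,-50.4,2.37,2.3,2.58,FALSE,running text gives b2 = 49.3; the tabulated 43.9 reproduces the printed vertex
MCAD,Trp166,C,-9.65,44.3,-49.1,2.30,2.25,2.41,FALSE,
MCAD,Trp166,D,-9.5,45,-51.9,2.37,2.33,2.54,FALSE,
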