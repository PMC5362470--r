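treat_row,treat_col,hr,lo,hi
TACE,TACE+EBRT,0.71,0.59,0.83
TACE,TACE+HIFU,0.25,0.22,0.28
TACE,TACE+PEI,0.51,0.46,0.56
TACE,TACE+RFA,0.53,0.42,0.63
TACE,TACE+RT,0.53,0.47,0.59
TACE,TACE+SOR,0.55,0.50,0.60
TACE,TARE-90Y,0.87,0.80,0.94
TACE,DEB-TACE,0.52,0.47,0.57
TACE,RFA,0.90,0.80,0.99
TACE,RT,0.44,0.34,0.54
TACE+PEI,PEI,2.02,1.77,2.35
TACE+RFA,RFA,1.90,1.66,2.22
TACE+RT,RT,5.56,4.44,7.41
PAI,PEI,1.78,0.93,1.60
PEI,RFA,0.43,0.35,0.50
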