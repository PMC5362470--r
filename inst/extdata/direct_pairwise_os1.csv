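treat_row,treat_col,hr,lo,hi
TACE,TACE+EBRT,0.73,0.56,0.90
TACE,TACE+HIFU,0.24,0.21,0.28
TACE,TACE+PEI,0.48,0.41,0.54
TACE,TACE+RFA,0.52,0.39,0.66
TACE,TACE+RT,0.52,0.45,0.60
TACE,TACE+SOR,0.47,0.45,0.49
TACE,TARE-90Y,0.88,0.80,0.97
TACE,DEB-TACE,0.51,0.46,0.57
TACE,PEI,0.91,0.78,1.04
TACE,RFA,0.84,0.67,1.00
TACE,RT,0.42,0.32,0.52
TACE+PEI,PEI,2.04,1.69,2.56
TACE+RFA,RFA,2.13,1.92,2.44
TACE+RT,RT,6.25,5.00,8.33
PAI,PEI,1.33,0.90,2.56
PEI,RFA,0.30,0.20,0.41
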