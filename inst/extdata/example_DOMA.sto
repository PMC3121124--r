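# STOCKHOLM 1.0
#=GF ID DOMA
#=GS A1_HUMAN AC Q00001
A1_HUMAN/3-10   ACDEFGHI
A2_HUMAN/5-12   ACDEFGHL
B1_MOUSE/1-8    ACDEYGHI
C1_YEAST/2-9    ACNEFGH-
D1_ECOLI/4-11   AC.EFGhI
//
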