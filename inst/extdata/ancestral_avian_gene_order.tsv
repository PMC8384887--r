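name	strand
trnF	H
rrnS	H
trnV	H
rrnL	H
trnL2	H
ND1	H
trnI	H
trnQ	L
trnM	H
ND2	H
trnW	H
trnA	L
trnN	L
trnC	L
trnY	L
COX1	H
trnS2	L
trnD	H
COX2	H
trnK	H
ATP8	H
ATP6	H
COX3	H
trnG	H
ND3	H
trnR	H
ND4L	H
ND4	H
trnH	H
trnS1	H
trnL1	H
ND5	H
CYTB	H
trnT	H
trnP	L
ND6	L
trnE	L
CR	H
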