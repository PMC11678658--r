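transcript_id	direction	groups
ARL6IP6	down	I,II,IIIA,IIIB,IIIC,VII
C11orf58	down	I,IIIA,IIIC,IIID,VII
RPN2	up	I,II,IIIA,IIIB,IIID
PDIA3	up	I,II,IIIA,IIIB,IIIC
VASN	up	I,IIIA,IIIB,IIID,VII
MINOS1	down	I,IIIB,IIIC,IIID,VII
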