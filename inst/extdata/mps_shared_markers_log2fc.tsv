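transcript_id	I	II	IIIA	IIIB	IIIC	IIID	IVA	IVB	VI	VII	IX
PFN1	3.4	3.7	3.5	3.6	3.7	3.5	3.6	3.7	3.5	3.7	2.9
ABHD5	-1.7	-1.2	-1.7	-1.0	-1.1	-0.7	-1.2	X	-1.0	-1.5	-1.1
ADAMTSL1	3.8	3.0	3.3	3.6	3.3	2.3	3.3	3.0	2.7	X	2.9
C1D	-1.2	-1.1	-1.5	-1.1	-1.4	-1.1	-1.4	-1.4	-1.0	X	-1.0
CAPG	2.7	X	4.7	2.0	4.3	2.8	4.2	4.1	3.8	4.3	4.6
LY6K	-3.8	-2.6	-1.8	-3.0	-3.6	-5.3	X	-4.3	-2.7	-3.8	-4.0
MFAP5	X	5.5	6.1	5.0	4.5	3.8	3.9	4.1	4.6	4.2	4.4
PLCB4	-1.5	-1.8	-0.9	-3.1	-1.7	X	-1.7	-3.0	-1.6	-0.9	-2.0
SH3BP5	1.4	1.3	1.8	1.4	1.1	X	0.9	1.0	1.3	1.2	1.4
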