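gene	copies	origin
trnC-GCA	1	native
trnE-UUC	2	native
trnG-GCC	1	native
trnI-CAU	1	native
trnK-UUU	1	native
trnL-UAA	1	native
trnM-CAU	2	native
trnP-UGG	1	native
trnS-GCU	1	native
trnS-UGA	1	native
trnT-UGU	1	native
trnY-GUA	1	native
trnD-GUC	1	cp-derived
trnF-GAA	2	cp-derived
trnH-GUG	1	cp-derived
trnL-CAA	1	cp-derived
trnM-CAU	2	cp-derived
trnN-GUU	1	cp-derived
trnQ-UUG	1	cp-derived
trnR-ACG	1	cp-derived
trnS-GGA	1	cp-derived
trnV-GAC	1	cp-derived
trnW-CCA	2	cp-derived
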