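gene	copies
trnA-UGC	2
trnC-GCA	1
trnD-GUC	1
trnE-UUC	1
trnF-GAA	1
trnG-UCC	1
trnH-GUG	1
trnI-CAU	1
trnI-GAU	2
trnK-UUU	1
trnL-CAA	1
trnL-GAG	1
trnL-UAA	1
trnL-UAG	1
trnM-CAU	3
trnN-GUU	2
trnP-UGG	1
trnQ-UUG	1
trnR-ACG	2
trnR-UCU	1
trnS-GCU	2
trnS-UGA	1
trnT-GGU	2
trnV-GAC	2
trnV-UAC	1
trnW-CCA	1
trnY-GUA	1
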