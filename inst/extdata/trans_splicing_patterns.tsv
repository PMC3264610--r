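species	nad1	nad2	nad5
Chara vulgaris	-*	+*	+*
Marchantia polymorpha	+*	++	++
Megaceros aenigmaticus	++++	+++	++++
Cycas taitungensis	+----	--+++	+++++
Triticum aestivum	----+	++---	+++++
Oryza sativa	+----	+++--	++---
Sorghum bicolor	+--+-	--+++	++-++
Tripsacum dactyloides	----+	++---	+++++
Zea mays	++++-	--+++	++---
Beta vulgaris	---+-	++---	+++--
Brassica napus	-++++	--+++	++---
Arabidopsis thaliana	-----	-----	-----
Nicotiana tabacum	+----	--+++	++-++
Vitis vinifera	+++--	+++++	-----
Boea hygrometrica	---++	-----	+++++
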