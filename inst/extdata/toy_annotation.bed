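chr1	1000	40000	tx_edge	0	+
chr1	50000	70000	tx_short	0	+
chr2	10000	50000	tx_ovlA	0	+
chr2	40000	90000	tx_ovlB	0	-
chrM	2000	38000	tx_chrM	0	+
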