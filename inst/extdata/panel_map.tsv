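# Female X genetic-map positions (cM) for the nine-locus panel.
# Synthetic within-group placement: group spans (0.763, 0.417, 1.906 cM)
# and midpoint separations (LG1-LG2 37.60, LG2-LG3 25.67 cM) match the
# published characterization; individual locus offsets are constructed.
locus	linkage_group	position_cM
X003	LG1	0.0000
X006	LG1	0.4000
X008	LG1	0.7630
X016	LG2	37.7730
X018	LG2	37.9600
X019	LG2	38.1900
X028	LG3	62.6985
X029	LG3	63.6000
X033	LG3	64.6045
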