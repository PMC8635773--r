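# Published allele frequencies of the nine-locus X-STR panel
# (Shanghai Han, n = 269 chromosomes: 127 males + 2 x 71 females).
# Frequencies are kept verbatim as printed (4 decimals, unnormalized).
locus	allele	frequency
X003	11	0.0112
X003	12	0.0297
X003	13	0.4126
X003	14	0.3011
X003	15	0.2268
X003	16	0.0112
X003	17	0.0074
X006	10	0.0260
X006	11	0.0967
X006	12	0.1078
X006	13	0.2454
X006	14	0.1190
X006	15	0.0446
X006	16	0.0669
X006	17	0.0409
X006	18	0.1450
X006	19	0.0743
X006	20	0.0297
X006	21	0.0037
X008	7	0.0186
X008	8	0.1599
X008	9	0.5465
X008	10	0.2268
X008	11	0.0483
X016	10	0.0223
X016	11	0.2045
X016	12	0.2193
X016	13	0.4424
X016	14	0.1078
X016	15	0.0037
X018	8	0.0037
X018	9	0.1859
X018	10	0.4126
X018	11	0.2825
X018	12	0.1004
X018	13	0.0149
X019	5	0.0186
X019	6	0.1190
X019	7	0.4572
X019	8	0.0372
X019	9	0.1152
X019	10	0.1784
X019	11	0.0520
X019	12	0.0149
X019	13	0.0074
X028	14	0.0037
X028	15	0.0149
X028	16	0.1152
X028	17	0.2825
X028	18	0.1970
X028	19	0.2007
X028	20	0.1004
X028	21	0.0409
X028	22	0.0149
X028	23	0.0186
X028	24	0.0112
X029	6	0.0074
X029	7	0.0149
X029	9	0.6097
X029	10	0.2677
X029	11	0.0706
X029	12	0.0260
X029	13	0.0037
X033	10	0.0781
X033	11	0.3346
X033	12	0.2454
X033	13	0.1413
X033	14	0.0372
X033	15	0.1041
X033	16	0.0297
X033	17	0.0297
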