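# Per-screen ridge regression coefficients for network genes prioritized
# as favorable or unfavorable across three psychiatric drug screens
# (in silico phagocytosis, zebrafish phenoscore, clinical efficacy), with
# the published consensus average (mean of absolute values, 4 decimals).
# Negative coefficients are favorable in the in silico screen only.
gene	direction	in_silico	zebrafish	clinical	reported_average
ABCG2	favorable	-0.0228	0.0012	0.2249	0.0830
SLC6A4	favorable	-0.0043	0.0128	0.1668	0.0613
GNAZ	favorable	-0.0906	0.0276	0.0173	0.0452
ADRA2A	favorable	-0.0761	0.0420	0.0173	0.0451
HTR1D	favorable	-0.0745	0.0002	0.0329	0.0359
HTR1E	favorable	-0.0745	0.0002	0.0329	0.0359
HTR1F	favorable	-0.0745	0.0002	0.0329	0.0359
HTR5A	favorable	-0.0745	0.0002	0.0329	0.0359
ADORA3	favorable	-0.0900	0.0144	0.0005	0.0350
ADRA2B	favorable	-0.0529	0.0334	0.0173	0.0345
ADRA2C	favorable	-0.0529	0.0334	0.0173	0.0345
DERL1	favorable	-0.0098	0.0484	0.0134	0.0239
CYP1A1	favorable	-0.0482	0.0111	0.0110	0.0235
ANXA1	favorable	-0.0513	0.0070	0.0105	0.0229
PDE4B	unfavorable	0.1172	-0.0364	-0.0191	0.0576
HTR1A	unfavorable	0.1355	-0.0143	-0.0105	0.0534
SLCO2B1	unfavorable	0.0651	-0.0341	-0.0004	0.0332
GABBR1	unfavorable	0.0303	-0.0187	-0.0191	0.0227
HTR2A	unfavorable	0.0148	-0.0019	-0.0362	0.0176
TAC1	unfavorable	0.0216	-0.0013	-0.0026	0.0085
F2	unfavorable	0.0155	-0.0023	-0.0026	0.0068
GRM5	unfavorable	0.0049	-0.0013	0.0110	0.0057
ADRA1D	unfavorable	0.0049	-0.0013	-0.0052	0.0038
NMBR	unfavorable	0.0049	-0.0013	0.0042	0.0035
GPR68	unfavorable	0.0049	-0.0013	-0.0042	0.0035
P2RY10	unfavorable	0.0049	-0.0013	-0.0042	0.0035
GRPR	unfavorable	0.0049	-0.0013	-0.0040	0.0034
PROKR2	unfavorable	0.0049	-0.0013	-0.0027	0.0030
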