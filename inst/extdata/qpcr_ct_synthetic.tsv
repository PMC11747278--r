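# Synthetic qPCR cycle-threshold fixture (three biological replicates per
# group, 18S-style internal reference).  Constructed to exercise the
# 2^-ddCt workflow; not measured data.
gene	group	replicate	ct_target	ct_reference
HMGR	underground	1	22.10	14.95
HMGR	underground	2	22.34	15.10
HMGR	underground	3	21.98	15.02
HMGR	aboveground	1	23.90	15.05
HMGR	aboveground	2	24.11	15.16
HMGR	aboveground	3	23.85	14.98
DXS	underground	1	20.45	15.01
DXS	underground	2	20.30	14.92
DXS	underground	3	20.61	15.08
DXS	aboveground	1	25.55	15.00
DXS	aboveground	2	25.72	15.11
DXS	aboveground	3	25.40	14.95
menE	underground	1	24.20	15.04
menE	underground	2	24.05	14.97
menE	underground	3	24.38	15.12
menE	aboveground	1	25.52	15.06
menE	aboveground	2	25.60	15.00
menE	aboveground	3	25.31	14.93
ACO	underground	1	23.01	15.00
ACO	underground	2	23.15	15.09
ACO	underground	3	22.90	14.96
ACO	aboveground	1	23.05	15.02
ACO	aboveground	2	23.20	15.10
ACO	aboveground	3	22.95	14.99
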