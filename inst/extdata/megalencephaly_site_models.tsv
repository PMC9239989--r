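gene	omega_m0	lnl_m0	lnl_m1a	lnl_m2a	m2a_prop_pos	m2a_omega_pos	lrt_printed	p_printed	padj_printed
AKT1	0.007	-3625.303	-3625.094	-3625.303	0	NA	0.000	1.000	1.000
AKT3	0.021	-2925.293	-2923.472	-2923.472	0	NA	0.000	1.000	1.000
BRWD3	0.074	-12041.425	-12017.838	-12017.838	0	NA	0.000	1.000	1.000
CCND2	0.024	-2207.414	-2207.403	-2207.414	0	NA	0.000	1.000	1.000
EXT2	0.062	-5732.827	-5704.928	-5704.913	0.036	1.062	0.030	0.985	0.985
GPC3	0.118	-4135.848	-4113.963	-4113.963	0	NA	0.000	1.000	1.000
HEPACAM	0.080	-3513.975	-3507.550	-3507.550	0	NA	0.000	1.000	1.000
KIF7	0.087	-13051.813	-12950.080	-12950.080	0	NA	0.000	1.000	1.000
MTOR	0.013	-18125.185	-18106.353	-18106.350	0	NA	0.006	1.000	1.000
OFD1	0.572	-9998.686	-9941.731	-9924.029	0.018	6.224	35.405	2e-8	3.2e-7
PIK3CA	0.030	-6964.649	-6946.226	-6946.230	0	NA	-0.009	1.000	1.000
PTEN	0.070	-2210.268	-2208.260	-2208.270	0	NA	0.000	1.000	1.000
RIN2	0.095	-7253.544	-7238.230	-7238.230	0	NA	0.000	1.000	1.000
SPRED1	0.120	-2754.241	-2753.040	-2753.040	0	NA	0.000	1.000	1.000
STRADA	0.114	-3582.065	-3572.440	-3572.440	0	NA	0.000	1.000	1.000
TBC1D7	0.139	-2518.094	-2512.990	-2512.990	0	NA	0.000	1.000	1.000
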