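guest	dG	dG_sem	dH	dH_sem	TdS	TdS_sem	dG_expt	dH_expt	TdS_expt
G1	-6.3	1.4	-7.6	0.1	-1.3	1.4	-7.1	-7.8	-0.8
G2	-9.6	0.6	-5.0	0.7	4.6	0.9	-9.9	-10.8	-0.9
G3	-10.2	1.9	-11.9	0.2	-1.7	1.7	-11.6	-13.6	-2.0
G4	-12.6	1.8	-11.7	0.4	1.0	1.5	-11.2	-15.8	-4.6
G5	-12.2	1.4	-14.0	0.02	-1.7	1.4	-12.3	-17.3	-5.0
G6	-15.3	1.0	-14.4	0.1	1.0	1.0	-14.1	-14.9	-0.8
G7	-9.0	0.4	-11.5	0.3	-2.5	0.1	-7.9	-8.3	-0.3
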