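# Default RNA dinucleotide physical-chemical property table (10 properties x 16 dinucleotides).
# Shift/Slide/Rise (Angstrom) and Tilt/Roll/Twist (degrees): representative A-form RNA helical
#   step parameters compiled from the structural literature, with reverse-complement symmetry
#   (shift and tilt change sign; slide, rise, roll, twist are invariant).
# Stacking_energy: nearest-neighbor stacking free energies (kcal/mol), Freier et al. 1986.
# Enthalpy (kcal/mol), Entropy (cal/mol/K), Free_energy (kcal/mol at 37C): Watson-Crick
#   nearest-neighbor parameters, Xia et al. 1998.
# Values are standardized (zero mean, unit population sd per property) before encoding;
# the table is a configurable input, not a fixed constant of the method.
property	AA	AC	AG	AU	CA	CC	CG	CU	GA	GC	GG	GU	UA	UC	UG	UU
Shift	-0.08	0.23	-0.04	0.00	0.11	-0.01	0.30	0.04	0.07	0.07	0.01	-0.23	0.00	-0.07	-0.11	0.08
Slide	-1.27	-1.43	-1.50	-1.36	-1.45	-1.78	-1.89	-1.50	-1.70	-1.39	-1.78	-1.43	-1.49	-1.70	-1.45	-1.27
Rise	3.18	3.24	3.32	3.24	3.09	3.32	3.30	3.32	3.38	3.22	3.32	3.24	3.30	3.38	3.09	3.18
Tilt	-0.8	0.5	-1.5	0.0	0.4	-0.4	0.0	1.5	-1.0	0.0	0.4	-0.5	0.0	1.0	-0.4	0.8
Roll	7.0	4.8	8.5	7.1	9.9	8.7	12.1	8.5	9.4	6.1	8.7	4.8	9.6	9.4	9.9	7.0
Twist	31.1	32.0	30.5	32.1	31.0	32.2	29.8	30.5	32.0	33.7	32.2	32.0	31.3	32.0	31.0	31.1
Stacking_energy	-0.9	-2.1	-1.7	-0.9	-1.8	-2.9	-2.0	-1.7	-2.3	-3.4	-2.9	-2.1	-1.1	-2.3	-1.8	-0.9
Enthalpy	-6.82	-11.40	-10.48	-9.38	-10.44	-13.39	-10.64	-10.48	-12.44	-14.88	-13.39	-11.40	-7.69	-12.44	-10.44	-6.82
Entropy	-19.0	-29.5	-27.1	-26.7	-26.9	-32.7	-26.7	-27.1	-32.5	-36.9	-32.7	-29.5	-20.5	-32.5	-26.9	-19.0
Free_energy	-0.93	-2.24	-2.08	-1.10	-2.11	-3.26	-2.36	-2.08	-2.35	-3.42	-3.26	-2.24	-1.33	-2.35	-2.11	-0.93
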