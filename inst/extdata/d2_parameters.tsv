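# DFT-D2 dispersion parameters: C6 coefficients (J nm^6 mol^-1) and van der
# Waals radii r0 (Angstrom) per element, H through Xe.
element	z	c6	r0
H	1	0.14	1.001
He	2	0.08	1.012
Li	3	1.61	0.825
Be	4	1.61	1.408
B	5	3.13	1.485
C	6	1.75	1.452
N	7	1.23	1.397
O	8	0.70	1.342
F	9	0.75	1.287
Ne	10	0.63	1.243
Na	11	5.71	1.144
Mg	12	5.71	1.364
Al	13	10.79	1.639
Si	14	9.23	1.716
P	15	7.84	1.705
S	16	5.57	1.683
Cl	17	5.07	1.639
Ar	18	4.61	1.595
K	19	10.80	1.485
Ca	20	10.80	1.474
Sc	21	10.80	1.562
Ti	22	10.80	1.562
V	23	10.80	1.562
Cr	24	10.80	1.562
Mn	25	10.80	1.562
Fe	26	10.80	1.562
Co	27	10.80	1.562
Ni	28	10.80	1.562
Cu	29	10.80	1.562
Zn	30	10.80	1.562
Ga	31	16.99	1.650
Ge	32	17.10	1.727
As	33	16.37	1.760
Se	34	12.64	1.771
Br	35	12.47	1.749
Kr	36	12.01	1.727
Rb	37	24.67	1.628
Sr	38	24.67	1.606
Y	39	24.67	1.639
Zr	40	24.67	1.639
Nb	41	24.67	1.639
Mo	42	24.67	1.639
Tc	43	24.67	1.639
Ru	44	24.67	1.639
Rh	45	24.67	1.639
Pd	46	24.67	1.639
Ag	47	24.67	1.639
Cd	48	24.67	1.639
In	49	37.32	1.672
Sn	50	38.71	1.804
Sb	51	38.44	1.881
Te	52	31.74	1.892
I	53	31.50	1.892
Xe	54	29.99	1.881
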