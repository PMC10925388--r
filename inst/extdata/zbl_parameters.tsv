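# Ziegler-Biersack-Littmark universal screening function constants.
# f(x) = c1 exp(-e1 x) + c2 exp(-e2 x) + c3 exp(-e3 x) + c4 exp(-e4 x)
# a0: screening length prefactor in Angstrom (0.8854 * Bohr radius);
# p: exponent of the Z dependence a_ij = a0 / (Z_i^p + Z_j^p).
name	value
c1	0.18175
c2	0.50986
c3	0.28022
c4	0.02817
e1	3.19980
e2	0.94229
e3	0.40290
e4	0.20162
a0	0.46850
p	0.23
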