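# Synthetic single-zeta Slater shell description for H, C, N, O pseudoatoms.
# These are generic single-zeta exponents of the Clementi-Raimondi type,
# NOT the values of any published pseudoatom databank: they are stand-in
# fixture parameters so that the package is self-contained. Exponents are
# density exponents (twice the orbital exponent) in bohr^-1 and are
# converted to A^-1 when loaded.
#
# columns:
#   element  Z  P_c  P_val  n_core zeta_core  n_val zeta_val  zeta_def n1 n2 n3 n4
H 1 0 1 0  0.00  0 2.00  2.26 1 2 2 2
C 6 2 4 0 11.34  2 3.18  3.18 2 2 3 4
N 7 2 5 0 13.33  2 3.84  3.84 2 2 3 4
O 8 2 6 0 15.32  2 4.47  4.47 2 2 3 4
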