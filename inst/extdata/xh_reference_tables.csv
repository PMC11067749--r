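# X-H bond lengths (Angstrom) from kinematical refinements against simulated
# data (table kin, reference = neutron 15 K) and dynamical refinements against
# experimental data (table dyn, reference = neutron 60 K), as printed in the
# source publication's tables; used as worked-example inputs for the ME/RMSD
# statistics.
table,bond,reference,IAM,TAAM,molecule_TAAM,crystal_TAAM
kin,N3-H3,1.0425,1.045,1.043,1.030,1.0467
kin,C5-H5,1.0812,1.101,1.076,1.084,1.0727
kin,C6-H6,1.0877,1.111,1.080,1.098,1.0790
kin,C7-H7a,1.0826,1.102,1.078,1.092,1.074
kin,C7-H7b,1.0878,1.113,1.0915,1.087,1.0989
dyn,N3-H3,1.0408,1.065,1.074,,1.084
dyn,C5-H5,1.0794,1.086,1.053,,1.067
dyn,C6-H6,1.0884,1.122,1.054,,1.127
dyn,C7-H7a,1.0817,1.120,1.078,,1.070
dyn,C7-H7b,1.0858,1.220,1.091,,1.100
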