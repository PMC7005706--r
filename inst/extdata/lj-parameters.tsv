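# pepsurf embedded reduced force field, nonbonded table v0.1.0
# 12-6 Lennard-Jones parameters per MM atom type; kcal/mol and Angstrom
# mixing: Lorentz-Berthelot; 1-4 scaling: LJ x 0.5, Coulomb x 1/1.2
# metal sites (AU) carry zero partial charge
type	eps	sigma
CT	0.1094	3.4
CAro	0.086	3.55
C	0.086	3.4
O	0.21	2.96
OH	0.2104	3.07
N	0.17	3.25
AU	5.29	2.629
OW	0.1521	3.1507
HW	0	1
LJ	1	3
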