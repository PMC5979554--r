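# Per-atom-type parameters of the AutoDock 4.2 free-energy model.
# These constants come from the published AutoDock 4.2 force-field tables,
# not from this package; substitute your own file to change them.
#
# columns:
#   type      AutoDock atom type token
#   radius    Rii, equilibrium distance of the like pair, Angstrom
#   well      eps_ii, well depth of the like pair, kcal/mol
#   solpar    atomic solvation parameter S_i (charge-free part)
#   volume    atomic volume V_i, Angstrom^3
#   hbond     0 = none, 1 = donor (H on O/N), 2 = acceptor
#   rhb       equilibrium distance of the 12-10 hydrogen bond, Angstrom
#   epshb     well depth of the 12-10 hydrogen bond, kcal/mol
#
# type radius well   solpar    volume  hbond rhb epshb
C   4.00 0.150 -0.00143 33.5103 0 0.0 0.0
A   4.00 0.150 -0.00052 33.5103 0 0.0 0.0
N   3.50 0.160 -0.00162 22.4493 0 0.0 0.0
NA  3.50 0.160 -0.00162 22.4493 2 1.9 5.0
O   3.20 0.200 -0.00251 17.1573 2 1.9 5.0
OA  3.20 0.200 -0.00251 17.1573 2 1.9 5.0
S   4.00 0.200 -0.00214 33.5103 0 0.0 0.0
SA  4.00 0.200 -0.00214 33.5103 2 2.5 1.0
H   2.00 0.020  0.00051  0.0000 0 0.0 0.0
HD  2.00 0.020  0.00051  0.0000 1 0.0 0.0
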