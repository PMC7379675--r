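# Illustrative electron stopping-power table for the parametric track model.
# Piecewise log-linear in (energy, LET); values approximate collision stopping
# of electrons in liquid water and are editable model inputs, not asserted
# ground truth.
# energy_mev, let_kev_um
energy_mev,let_kev_um
0.0001,30.0
0.001,12.6
0.01,2.26
0.1,0.41
0.5,0.21
1.0,0.185
3.0,0.185
6.0,0.19
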