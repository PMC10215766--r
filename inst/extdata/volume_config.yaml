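# Example configuration for the `volume` subcommand: the potassium
# polysulfide / Sylgard 184 layered-cuvette assay.
D_m2_per_s: 8.901e-11
c0_mol_per_m3: 159.9
c_threshold_mol_per_m3: 24.23
thickness_mm: "1,2,3,4,5,6,7,8,9,10"
n_grid: 201
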