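# Drosophila S2 doublet centriole preset (176 nm = nearest 8 nm dimer
# multiple to the mean 175 nm length).
name: s2
n_blades: 9
radius_proximal_nm: 96.0
radius_distal_nm: 96.0
blade_tilt_proximal_deg: 50
blade_tilt_distal_deg: 50
length_nm: 176
domain_boundary_nm: 176
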