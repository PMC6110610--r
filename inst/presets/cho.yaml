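# CHO (hamster) triplet centriole preset.
# Blade reference radii are calibrated so the 20%-of-max outer-envelope
# diameter convention yields the nominal ensemble diameters.
name: cho
n_blades: 9
radius_proximal_nm: 109.6
radius_distal_nm: 99.7
blade_tilt_proximal_deg: 50
blade_tilt_distal_deg: 65
length_nm: 440
domain_boundary_nm: 200
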