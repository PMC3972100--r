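# HSA site definitions (1N5U-aligned frame, Angstrom)
site_I centroid 30.5 13.1 9.7
site_I inner_box 10
site_I outer_box 30
site_II centroid 10.25 2.11 -13.75
site_II inner_box 10
site_II outer_box 30
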