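name,value
dry_matter_fraction,0.47
dry_matter_min,0.31
dry_matter_max,0.62
tattoo_z_top_mm,1.25
tattoo_z_bottom_mm,1.55
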