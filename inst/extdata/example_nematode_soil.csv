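mesocosm_id,total_count,fresh_soil_mass,dry_fraction,dry_soil_density
M001,128,20,0.7913952835049683,1.2287110456320185
M002,157,20,0.8525096566600635,1.2068245406014326
M003,6568,20,0.8034924083812843,1.2457107994484065
M004,5968,20,0.8415275947475783,1.1099586841023341
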