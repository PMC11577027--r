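node_id,resource_type,pool_biomass
plant,plant,NA
microbe,microbe,NA
detritus,detritus,NA
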