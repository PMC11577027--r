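taxon_id,fauna_class,frac_animal,frac_plant,frac_microbe,frac_detritus,agility,defended,stratum,metab_ln_x0,metab_a,metab_E,lw_form,lw_a,lw_b,fixed_body_mass
lumbricidae,macrofauna,0,0,0.1,0.9,0.2,FALSE,euedaphic,23.055,0.695,0.686,length_width,1.9,0.92,NA
lithobiidae,macrofauna,1,0,0,0,0.6,FALSE,epigeic,23.055,0.695,0.686,length_width,1.2,0.95,NA
oppiidae,mesofauna,0,0,0.4,0.6,0.2,TRUE,hemiedaphic,23.055,0.695,0.686,power,0.04,2.5,NA
isotomidae,mesofauna,0,0.1,0.5,0.4,0.8,FALSE,hemiedaphic,23.055,0.695,0.686,power,0.03,2.4,NA
gamasina,mesofauna,1,0,0,0,0.7,FALSE,hemiedaphic,23.055,0.695,0.686,power,0.05,2.5,NA
enchytraeidae,mesofauna,0,0,0.3,0.7,0.3,FALSE,euedaphic,23.055,0.695,0.686,power,0.02,2.2,NA
rhabditidae,nematode,0,0,1,0,0.2,FALSE,euedaphic,23.055,0.695,0.686,NA,NA,NA,4e-4
aphelenchidae,nematode,0,0,1,0,0.2,FALSE,euedaphic,23.055,0.695,0.686,NA,NA,NA,6e-4
dorylaimidae,nematode,0.5,0,0.5,0,0.3,FALSE,euedaphic,23.055,0.695,0.686,NA,NA,NA,0.003
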