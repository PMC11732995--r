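trait,full_name,source,unit,is_disease,nonnegative
Biomass_bio,above-ground dry mass at maturity,50 cm cut,g/m2,FALSE,TRUE
Harvest_Index_bio,harvest index,50 cm cut,ratio,FALSE,TRUE
Grain_per_spike_bio,grains per spike,50 cm cut,number,FALSE,TRUE
Plantheight_bio,plant height,50 cm cut,cm,FALSE,TRUE
Seedyield_bio,grain yield,50 cm cut,g/m2,FALSE,TRUE
Spike_number_bio,spike number,50 cm cut,number/m2,FALSE,TRUE
TGW_bio,thousand grain weight,50 cm cut,g,FALSE,TRUE
BBCH59,day when 75% of the ears are visible,whole plot,day of year,FALSE,TRUE
BBCH87,day when 75% hard dough,whole plot,day of year,FALSE,TRUE
Biomass,above-ground dry mass at maturity,whole plot,dt/ha,FALSE,TRUE
Crude_protein,crude protein percentage per grain dry mass,whole plot,%,FALSE,TRUE
DTR,leaf tan spot,whole plot,% leaf area,TRUE,TRUE
Falling_number,falling number,whole plot,s,FALSE,TRUE
Fusarium,fusarium head blight,whole plot,% spike,TRUE,TRUE
Grain,number of grains per unit area,whole plot,number x 10^5/ha,FALSE,TRUE
Leaf_rust,leaf rust,whole plot,% leaf area,TRUE,TRUE
Powdery_mildew,powdery mildew,whole plot,% leaf area,TRUE,TRUE
Protein_yield,grain protein yield,whole plot,dt/ha,FALSE,TRUE
Sedimentation,sedimentation,whole plot,ml,FALSE,TRUE
Seedyield,grain yield,whole plot,dt/ha,FALSE,TRUE
Septoria,leaf spot (Septoria),whole plot,% leaf area,TRUE,TRUE
Straw,above ground biomass minus grain yield,whole plot,dt/ha,FALSE,TRUE
Stripe_rust,stripe rust,whole plot,% leaf area,TRUE,TRUE
TGW,thousand grain weight,whole plot,g,FALSE,TRUE
TFI,total fungal infection area,derived,% area (summed),FALSE,TRUE
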