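# ricenm packaged fixture: three worked-example farmer interviews
field_id,district,acz,season,year,water_regime,variety_name,growth_duration_days,seedling_age_days,transplant_delay_days,historical_yield_GYR,variety_yield_ceiling,previous_crop_yield,residue_retained_fraction,selected_products,farmer_applies_zinc
F001,Cuttack,east_south_eastern_coastal_plain,kharif,2014,irrigated,Swarna,140,25,0,4.6,NA,4.5,0.15,urea;DAP;MOP,FALSE
F002,Mayurbhanj,north_central_plateau,rabi,2013-2014,irrigated,Lalat,125,21,0,3.7,NA,3.5,0.15,urea;DAP;MOP,FALSE
F003,Bhadrak,north_eastern_coastal_plain,kharif,2015,rainfed,Pooja,150,30,14,2.0,NA,0,0,urea;SSP;MOP,TRUE
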