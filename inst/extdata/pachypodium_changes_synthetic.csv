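species,iucn_category,category_start,current_km2,net_change_pct_ssp245,net_change_pct_ssp585
P_inopinatum,CR,CR,1200,-40,-45
P_baronii,EN,EN,8500,180,190
P_mikea,EN,EN,5200,-100,-100
P_brevicaule,VU,VU,900,-95,-96
P_lealii,VU,VU,391130,-35,-45
P_sofiense,VU,VU,14200,-50,-78
P_geayi,LC,LC,52000,-92,-94
P_lamerei,LC,LC,68000,-60,-75
P_namaquanum,LC,LC,45000,-20,-28
P_rutenbergianum,LC,LC,72000,50,80
P_saundersii,NE,NT,161290,-80,-85
P_decaryi,NE,NT,1500,300,450
P_densiflorum,NE,NT,22000,-38,-48
P_succulentum,NE,VU,301190,30,60
P_ambongense,NE,VU,342.8,-30,-42
P_horombense,NE,VU,9800,-100,-100
P_bispinosum,NE,VU,56000,-25,-29
P_windsorii,NE,VU,610,250,420
P_menabeum,NE,VU,2300,-100,-100
P_rosulatum,NE,VU,30500,-15,-22
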