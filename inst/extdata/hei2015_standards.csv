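index,component,label,direction,max_points,zero_score,full_score,zero_score_female,full_score_female,basis,units,special_rule
HEI-2015,hei_total_fruits,Total Fruits,adequacy,5,0,0.8,NA,NA,density_1000,cup_eq,none
HEI-2015,hei_whole_fruits,Whole Fruits,adequacy,5,0,0.4,NA,NA,density_1000,cup_eq,none
HEI-2015,hei_total_vegetables,Total Vegetables,adequacy,5,0,1.1,NA,NA,density_1000,cup_eq,none
HEI-2015,hei_greens_beans,Greens and Beans,adequacy,5,0,0.2,NA,NA,density_1000,cup_eq,none
HEI-2015,hei_whole_grains,Whole Grains,adequacy,10,0,1.5,NA,NA,density_1000,oz_eq,none
HEI-2015,hei_dairy,Dairy,adequacy,10,0,1.3,NA,NA,density_1000,cup_eq,none
HEI-2015,hei_total_protein,Total Protein Foods,adequacy,5,0,2.5,NA,NA,density_1000,oz_eq,none
HEI-2015,hei_seafood_plant_protein,Seafood and Plant Proteins,adequacy,5,0,0.8,NA,NA,density_1000,oz_eq,none
HEI-2015,hei_fatty_acid_ratio,Fatty Acids (PUFA+MUFA)/SFA,adequacy,10,1.2,2.5,NA,NA,as_is,ratio,none
HEI-2015,hei_refined_grains,Refined Grains,moderation,10,4.3,1.8,NA,NA,density_1000,oz_eq,none
HEI-2015,hei_sodium,Sodium,moderation,10,2.0,1.1,NA,NA,density_1000,g,none
HEI-2015,hei_added_sugars,Added Sugars,moderation,10,26,6.5,NA,NA,as_is,pct_energy,none
HEI-2015,hei_saturated_fats,Saturated Fats,moderation,10,16,8,NA,NA,as_is,pct_energy,none
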