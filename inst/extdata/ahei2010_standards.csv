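index,component,label,direction,max_points,zero_score,full_score,zero_score_female,full_score_female,basis,units,special_rule,band_low,band_high,band_high_female,zero_above,zero_above_female,nonconsumer_points
AHEI-2010,ahei_vegetables,Vegetables,adequacy,10,0,5,NA,NA,per_day,servings,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_fruit,Fruit,adequacy,10,0,4,NA,NA,per_day,servings,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_whole_grains,Whole Grains,adequacy,10,0,90,0,75,per_day,g,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_nuts_legumes,Nuts and Legumes,adequacy,10,0,1,NA,NA,per_day,servings,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_long_chain_fats,Long-Chain Omega-3 Fats (EPA+DHA),adequacy,10,0,250,NA,NA,per_day,mg,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_pufa,Polyunsaturated Fats,adequacy,10,2,10,NA,NA,as_is,pct_energy,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_ssb_juice,Sugar-Sweetened Beverages and Fruit Juice,moderation,10,1,0,NA,NA,per_day,servings,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_red_processed_meat,Red and Processed Meat,moderation,10,1.5,0,NA,NA,per_day,servings,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_sodium,Sodium,moderation,10,3337,1112,NA,NA,per_day,mg,none,NA,NA,NA,NA,NA,NA
AHEI-2010,ahei_alcohol,Alcohol,special,10,NA,NA,NA,NA,per_day,drinks,adult-alcohol-band,0.5,2.0,1.5,3.5,2.5,2.5
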