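food_id,portion_label,grams
rice_cooked,small,150
rice_cooked,typical,250
rice_cooked,large,350
noodles_rice,typical,200
fish_freshwater,typical,80
pork_lean,typical,70
chicken,typical,75
egg_chicken,one,50
morning_glory,typical,60
mango_ripe,typical,120
banana,one,100
fish_sauce,typical,10
oil_vegetable,typical,9
sugar_palm,typical,8
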