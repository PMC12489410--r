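food_id,measure_label,grams
rice_cooked,rice_serving_spoon,55
rice_cooked,bowl_small,180
rice_cooked,bowl_large,300
fish_sauce,eating_spoon,10
fish_sauce,teaspoon,5
oil_vegetable,eating_spoon,9
sugar_palm,teaspoon,4
noodles_rice,bowl_small,160
banana,piece,100
egg_chicken,piece,50
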