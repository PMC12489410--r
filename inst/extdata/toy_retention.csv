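nutrient,cooking_method,factor
thiamine,boiled,0.5
thiamine,fried,0.7
riboflavin,boiled,0.85
riboflavin,fried,0.9
niacin,boiled,0.8
vitamin_b6,boiled,0.75
vitamin_b12,boiled,0.9
vitamin_c,boiled,0.6
vitamin_c,fried,0.75
dfe,boiled,0.7
dfe,fried,0.8
vitamin_a_re,fried,0.9
potassium,boiled,0.85
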