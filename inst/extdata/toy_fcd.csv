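food_id,name,group,energy,protein,fat,carbohydrate,fiber,alcohol,vitamin_a_re,thiamine,riboflavin,niacin,vitamin_b6,vitamin_b12,vitamin_c,dfe,calcium,phosphorus,sodium,potassium,iron,zinc
rice_cooked,"Rice, white, cooked",Cereals,130,2.7,0.3,28,0.4,0,0,0.02,0.01,0.4,0.09,0,0,3,10,43,1,35,0.2,0.5
rice_raw,"Rice, white, raw",Cereals,350,7,0.6,78,1.3,0,0,0.4,0.05,1.6,0.16,0,0,8,28,115,5,115,0.8,1.1
noodles_rice,"Rice noodles, cooked",Cereals,109,0.9,0.2,25,0.9,0,0,0.01,0.01,0.2,0.01,0,0,1,4,20,19,4,0.1,0.2
fish_freshwater,"Freshwater fish, raw",Fish,105,18.5,3,0,0,0,30,0.08,0.07,2.5,0.2,1.5,0,15,50,200,60,330,0.9,0.8
pork_lean,"Pork, lean, raw",Meat,145,21,6.5,0,0,0,2,0.7,0.2,4.8,0.45,0.6,0.7,5,6,200,60,350,0.9,2
chicken,"Chicken, flesh, raw",Meat,165,20,9,0,0,0,16,0.06,0.12,6.8,0.35,0.3,0,6,11,180,70,255,0.9,1.4
egg_chicken,"Egg, chicken, whole",Eggs,143,12.6,9.5,0.7,0,0,160,0.04,0.46,0.07,0.17,0.9,0,47,56,198,142,138,1.8,1.3
morning_glory,"Water spinach, raw",Vegetables,19,2.6,0.2,3.1,2.1,0,315,0.03,0.1,0.9,0.1,0,55,57,77,39,113,312,1.7,0.2
mango_ripe,"Mango, ripe",Fruit,60,0.8,0.4,15,1.6,0,54,0.03,0.04,0.7,0.12,0,36,43,11,14,1,168,0.2,0.1
banana,"Banana, ripe",Fruit,89,1.1,0.3,22.8,2.6,0,3,0.03,0.07,0.7,0.37,0,8.7,20,5,22,1,358,0.3,0.2
fish_sauce,"Fish sauce",Condiments,35,5,0,3.6,0,0,0,0.01,0.06,2.3,0.04,0.5,0.5,17,43,7,7850,288,0.8,0.2
oil_vegetable,"Vegetable oil",Fats,884,0,100,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
sugar_palm,"Palm sugar",Sugars,380,0,0,98,0,0,0,0,0.01,0.1,0.01,0,0,1,30,5,15,90,0.5,0.1
water,"Water, plain",Beverages,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
rice_beer,"Rice beer",Beverages,40,0.3,0,2.5,0,3.8,0,0,0.02,0.3,0.03,0,0,4,4,14,4,27,0,0
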