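typo,correct
coffeee,coffee
coffe,coffee
cofee,coffee
capuccino,cappuccino
expresso,espresso
avacado,avocado
avocadoe,avocado
bannana,banana
bananna,banana
brocoli,broccoli
brocolli,broccoli
tomatoe,tomato
potatoe,potato
yoghurt,yogurt
yougurt,yogurt
chese,cheese
cheeze,cheese
chiken,chicken
chickn,chicken
sandwhich,sandwich
sandwitch,sandwich
spagetti,spaghetti
spagheti,spaghetti
omelet,omelette
omlette,omelette
humus,hummus
quinua,quinoa
zuchini,zucchini
zuccini,zucchini
cucmber,cucumber
letuce,lettuce
strawbery,strawberry
bluberry,blueberry
rasberry,raspberry
musrhoom,mushroom
mushroon,mushroom
pb,peanut butter
oj,orange juice
choc,chocolate
veg,vegetable
smothie,smoothie
ceral,cereal
cerial,cereal
oatmel,oatmeal
granloa,granola
croisant,croissant
bagle,bagel
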