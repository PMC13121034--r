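phrase,type,canonical_name
coffee,beverage,
salad,food,
egg,food,
chicken,food,
cheese,food,
rice,food,
milk,beverage,
bread,food,
banana,food,
apple,food,
yogurt,food,
tomato,food,
tea,beverage,
butter,food,
potato,food,
avocado,food,
chocolate,food,
almond,food,
carrot,food,
pasta,food,
sandwich,food,
oatmeal,food,
peanut butter,food,
broccoli,food,
orange,food,
cucumber,food,
strawberry,food,
spinach,food,
onion,food,
water melon,food,watermelon
watermelon,food,
wine,beverage,
cracker,food,
turkey,food,
soup,food,
bacon,food,
beef,food,
toast,food,
hummus,food,
beer,beverage,
blueberry,food,
cereal,food,
ice cream,food,
juice,beverage,
pizza,food,
salmon,food,
granola,food,
mushroom,food,
bagel,food,
cookie,food,
pepper,food,
steak,food,
orange juice,beverage,
pork,food,
grape,food,
tortilla,food,
lettuce,food,
shrimp,food,
bean,food,
corn,food,
pancake,food,
burger,food,
kale,food,
celery,food,
tuna,food,
cashew,food,
black coffee,beverage,
muffin,food,
honey,food,
taco,food,
quinoa,food,
peach,food,
oat,food,
lemon,food,
fries,food,
zucchini,food,
walnut,food,
sausage,food,
pea,food,
chip,food,
smoothie,beverage,
red wine,beverage,
white wine,beverage,
mango,food,
cauliflower,food,
spaghetti,food,
pear,food,
ham,food,
noodle,food,
curry,food,
tofu,food,
raspberry,food,
fish,food,
popcorn,food,
latte,beverage,
pineapple,food,
asparagus,food,
lime,food,
wrap,food,
peanut,food,
almond milk,beverage,
dark chocolate,food,
waffle,food,
cherry,food,
croissant,food,
black tea,beverage,
green tea,beverage,
herbal tea,beverage,
lentil,food,
pretzel,food,
sweet potato,food,
kombucha,beverage,
soda,beverage,
coconut,food,
pistachio,food,
date,food,
fig,food,
olive,food,
hot dog,food,
burrito,food,
sushi,food,
dumpling,food,
ramen,food,
guacamole,food,
salsa,food,
crab,food,
lobster,food,
oyster,food,
duck,food,
lamb,food,
venison,food,
meatball,food,
lasagna,food,
ravioli,food,
gnocchi,food,
pesto,food,
risotto,food,
paella,food,
falafel,food,
pita,food,
naan,food,
biryani,food,
enchilada,food,
quesadilla,food,
nacho,food,
chili,food,
stew,food,
casserole,food,
omelette,food,
frittata,food,
scone,food,
donut,food,
brownie,food,
cupcake,food,
pie,food,
cake,food,
pudding,food,
custard,food,
gelato,food,
sorbet,food,
fudge,food,
caramel,food,
jam,food,
jelly,food,
syrup,food,
maple syrup,food,
cream,food,
sour cream,food,
cottage cheese,food,
cream cheese,food,
mozzarella,food,
cheddar,food,
parmesan,food,
feta,food,
brie,food,
gouda,food,
ricotta,food,
edamame,food,
chickpea,food,
couscous,food,
barley,food,
millet,food,
buckwheat,food,
rye,food,
sourdough,food,sourdough bread
sourdough bread,food,
whole wheat bread,food,bread
whole grain bread,food,bread
white bread,food,bread
scrambled egg,food,egg
boiled egg,food,egg
fried egg,food,egg
poached egg,food,egg
grilled chicken,food,chicken
roast chicken,food,chicken
chicken breast,food,chicken
melted cheese,food,cheese
swiss cheese,food,cheese
brown rice,food,rice
white rice,food,rice
fried rice,food,rice
green salad,food,salad
caesar salad,food,salad
fruit salad,food,salad
iced coffee,beverage,coffee
cold brew,beverage,coffee
decaf coffee,beverage,coffee
espresso,beverage,
cappuccino,beverage,
mocha,beverage,
hot chocolate,beverage,
lemonade,beverage,
iced tea,beverage,tea
chai,beverage,
chai tea,beverage,chai
matcha,beverage,
cider,beverage,
whiskey,beverage,
vodka,beverage,
gin,beverage,
rum,beverage,
cocktail,beverage,
margarita,beverage,
champagne,beverage,
prosecco,beverage,
protein shake,beverage,
milkshake,beverage,
energy drink,beverage,
sports drink,beverage,
coconut water,beverage,
oat milk,beverage,
soy milk,beverage,
skim milk,beverage,milk
whole milk,beverage,milk
paprika,food,
salt,food,
sugar,food,
olive oil,food,
vegetable oil,food,
coconut oil,food,
soy sauce,food,
oyster sauce,food,
hot sauce,food,
ketchup,food,
mustard,food,
mayonnaise,food,
vinegar,food,
garlic,food,
ginger,food,
cinnamon,food,
basil,food,
oregano,food,
cumin,food,
turmeric,food,
flour,food,
ranch dressing,food,
salad dressing,food,
gravy,food,
relish,food,
breakfast,food,
lunch,food,
dinner,food,
snack,food,
meal,food,
brunch,food,
appetizer,food,
dessert,food,
meat,food,
protein,food,
fruit,food,
vegetable,food,
berry,food,
seed,food,
nut,food,
leftover,modifier,
warm,modifier,
hot,modifier,
cold,modifier,
grilled,modifier,
spicy,modifier,
fresh,modifier,
freshly squeezed,modifier,
baked,modifier,
roasted,modifier,
fried,modifier,
steamed,modifier,
homemade,modifier,
organic,modifier,
sugar free,modifier,
gluten free,modifier,
without sugar,modifier,
low fat,modifier,
mini,modifier,
large,modifier,
small,modifier,
melted,modifier,
iced,modifier,
nothing,stopword,
eat,stopword,
ate,stopword,
drink,stopword,
drank,stopword,
food,stopword,
having,stopword,
more,stopword,
another,stopword,
again,stopword,
same,stopword,
usual,stopword,
water,water,
tap water,water,
sparkling water,water,
mineral water,water,
club soda,water,
seltzer,water,
dasani,water,
vitamin,medication,
vitamin c,medication,
vitamin d,medication,
multivitamin,medication,
ibuprofen,medication,
aspirin,medication,
probiotic,medication,
melatonin,medication,
fish oil,medication,
magnesium,medication,
toothpaste,selfcare,
mouthwash,selfcare,
gum,selfcare,
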