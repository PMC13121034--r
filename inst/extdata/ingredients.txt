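salt
pepper
sugar
paprika
olive oil
vegetable oil
coconut oil
soy sauce
oyster sauce
hot sauce
ketchup
mustard
mayonnaise
vinegar
garlic
ginger
cinnamon
basil
oregano
cumin
turmeric
flour
ranch dressing
salad dressing
gravy
relish
honey
syrup
maple syrup
jam
jelly
pesto
salsa
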