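dinner
breakfast
lunch
snack
meat
protein
fruit
berry
seed
vegetable
appetizer
brunch
dessert
meal
leftover
nut
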