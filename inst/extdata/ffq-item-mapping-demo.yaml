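# Minimal demonstration mapping of FFQ items to candidate food groups
# (synthetic excerpt; a full instrument maps ~145 items to 33 groups).
wholegrain bread: wholegrains
macaroni: wholegrains
spaghetti: wholegrains
rice: wholegrains
lettuce: vegetables
tomato: vegetables
carrots: root_vegetables
sausage: processed_meat
ham: processed_meat
chips: other_processed_foods
buns/cakes: other_processed_foods
ice cream: other_processed_foods
red wine: wine
white wine: wine
peanuts: nuts
almonds: nuts
lentils: legumes
brown beans: legumes
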