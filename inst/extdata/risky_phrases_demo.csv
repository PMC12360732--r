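phrase,category,subcategory
hook up,sex_related,hookup_seeking
hookup,sex_related,hookup_seeking
hmu,sex_related,hookup_seeking
dtf,sex_related,hookup_seeking
nsa fun,sex_related,hookup_seeking
looking to play,sex_related,hookup_seeking
come over tonight,sex_related,hookup_seeking
raw,sex_related,condomless
bareback,sex_related,condomless
bb only,sex_related,condomless
no condom,sex_related,condomless
party and play,drug_related,party_context
pnp,drug_related,party_context
partying,drug_related,party_context
looking to party,drug_related,party_context
tina,drug_related,stimulant_use
crystal,drug_related,stimulant_use
ice cold stuff,drug_related,stimulant_use
spun,drug_related,stimulant_use
clouds,drug_related,stimulant_use
molly,drug_related,club_drugs
poppers,drug_related,club_drugs
g water,drug_related,club_drugs
slamming,drug_related,injection
point slam,drug_related,injection
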