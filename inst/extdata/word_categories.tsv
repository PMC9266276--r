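# Default word-category lists for review frequency profiling.
# Curated for this artifact (the delta words flavor, flavour, saltish, tart,
# tangy, biter are included in taste). Edit or replace freely.
category	word
taste	sweet
taste	sweets
taste	sweetness
taste	sweeter
taste	sweetest
taste	sweetened
taste	sweetener
taste	sweeteners
taste	salty
taste	saltish
taste	sour
taste	bitter
taste	biter
taste	umami
taste	savory
taste	savoury
taste	tart
taste	tangy
taste	flavor
taste	flavour
taste	taste
taste	tastes
taste	tasty
taste	tasteless
taste	delicious
taste	yummy
texture	texture
texture	crunchy
texture	crispy
texture	creamy
texture	chewy
texture	smooth
texture	gritty
texture	soggy
texture	mushy
texture	dense
texture	fluffy
texture	sticky
price	price
price	prices
price	cheap
price	cheaper
price	expensive
price	overpriced
price	cost
price	value
price	bargain
price	deal
customer service	shipping
customer service	shipped
customer service	delivery
customer service	delivered
customer service	arrived
customer service	packaging
customer service	package
customer service	refund
customer service	seller
customer service	service
customer service	order
customer service	ordered
health	health
health	healthy
health	nutrition
health	nutritious
health	calories
health	calorie
health	diet
health	keto
health	gluten
health	vitamins
health	protein
health	fiber
olfaction	smell
olfaction	smells
olfaction	scent
olfaction	aroma
olfaction	odor
olfaction	odour
olfaction	fragrance
chemesthesis	spicy
chemesthesis	pungent
chemesthesis	tingling
chemesthesis	burning
chemesthesis	cooling
chemesthesis	menthol
chemesthesis	fiery
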