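# Sweetener ontology: canonical name, caloric class, synonyms (pipe-separated,
# matched against consecutive normalized ingredient tokens).
# caloric_class is one of: caloric, non-caloric, sugar alcohol, sugar fiber
canonical_name	caloric_class	synonyms
sucrose	caloric	sucrose|sugar|cane sugar|organic cane sugar|evaporated cane juice|beet sugar|brown sugar|raw sugar|turbinado sugar|powdered sugar|confectioners sugar|invert sugar
glucose	caloric	glucose|dextrose|glucose syrup
fructose	caloric	fructose|crystalline fructose
lactose	caloric	lactose
corn syrup	caloric	corn syrup|corn syrup solids|light corn syrup|dark corn syrup
high fructose corn syrup	caloric	high fructose corn syrup|hfcs
honey	caloric	honey|raw honey
maple syrup	caloric	maple syrup|pure maple syrup
agave	caloric	agave|agave nectar|agave syrup
molasses	caloric	molasses|blackstrap molasses
sucralose	non-caloric	sucralose|splenda
steviol glycosides	non-caloric	stevia|steviol glycosides|stevia extract|stevia leaf extract|rebaudioside a|reb a
aspartame	non-caloric	aspartame
acesulfame potassium	non-caloric	acesulfame potassium|acesulfame k|ace k
saccharin	non-caloric	saccharin|sodium saccharin
monk fruit extract	non-caloric	monk fruit|monk fruit extract|luo han guo
erythritol	sugar alcohol	erythritol
xylitol	sugar alcohol	xylitol
sorbitol	sugar alcohol	sorbitol
maltitol	sugar alcohol	maltitol|maltitol syrup
inulin	sugar fiber	inulin|chicory root fiber|chicory root extract
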