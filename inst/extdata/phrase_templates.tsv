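# Text templates for the synthetic review-corpus generator. {product} is
# replaced by the product name. Kinds:
#   oversweet  - genuine oversweetness complaint about the purchased product
#   decoy      - contains an oversweet phrase that refers to OTHER products
#   under-sweet, neutral, sweet_only, none - non-oversweet review kinds
# Decoy templates carry comparison markers (other, brands, unlike, mixes,
# compared); real complaints carry disposal/aversion markers instead, so a
# bag-of-words classifier has a learnable, deterministic signal.
kind	text
oversweet	way too sweet for me, i could not finish this {product}
oversweet	this {product} is cloyingly sweet and sits heavy, one bite was plenty
oversweet	sickly sweet syrup flavor, the {product} went straight to the trash
oversweet	much too sweet, completely overpowering, it ruins the {product} for me
oversweet	the {product} tastes unbearably sweet, got a headache after one serving
oversweet	disgustingly sweet, i had to throw the rest of this {product} away
oversweet	overly sweet to the point of being inedible, skip this {product}
oversweet	too sweet for my taste, ended up tossing half of the {product}
decoy	i have had {product} from other brands that are too sweet, this one is very good
decoy	unlike other brands which are way too sweet, this {product} is just right
decoy	most similar products are much too sweet, but this {product} is balanced
decoy	i switched from another brand that was sickly sweet, this {product} is great
decoy	compared to the competition this {product} wins, the others are overly sweet
decoy	other mixes i tried were far too sweet, this one works well for us
under-sweet	the {product} is not sweet enough for me, it needed more sweetness
under-sweet	barely sweet at all, i add honey to my {product} every time
under-sweet	this {product} lacks sweetness, a bit bland for my taste
under-sweet	hardly sweet, i wish the {product} had more flavor
under-sweet	could be sweeter in my opinion, otherwise the {product} is fine
neutral	the {product} is perfectly sweet, just the way we like it
neutral	not too sweet, and the {product} has a great texture
neutral	pleasantly sweet with a mild flavor, the {product} works well in coffee
neutral	just sweet enough, my family enjoys this {product} every morning
neutral	naturally sweet and very fresh, will buy the {product} again
neutral	nice sweetness and a clean aftertaste, the {product} is a staple here
sweet_only	the {product} tastes sweet today, arrived quickly and well packed
sweet_only	my kids love how sweet this {product} smells when baking
sweet_only	a sweet snack for road trips, the {product} travels well
sweet_only	sweet little {product}, my kids ask for it every week
none	great {product}, fast shipping and a fair price, would order again
none	the texture of this {product} is crunchy and the flavor is rich
none	decent {product} for the price, packaging could be sturdier
none	my dog loves this {product}, we have been buying it for years
none	arrived on time, the {product} matches the description, no complaints
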