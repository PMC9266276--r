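# Seed phrases for the sweetness-level lexicon, before expansion with
# negations, misspellings and exclusion suffixes. Every surface contains a
# sweet-family word. Levels: oversweet, under-sweet, neutral, excluded.
# Curated for this artifact; not a verbatim reproduction of any published list.
surface	level
too sweet	oversweet
way too sweet	oversweet
much too sweet	oversweet
far too sweet	oversweet
just too sweet	oversweet
really too sweet	oversweet
simply too sweet	oversweet
entirely too sweet	oversweet
a bit too sweet	oversweet
a little too sweet	oversweet
a tad too sweet	oversweet
too sweet for me	oversweet
too sweet for my taste	oversweet
too sweet for us	oversweet
overly sweet	oversweet
over sweet	oversweet
oversweet	oversweet
oversweetened	oversweet
over sweetened	oversweet
too sweetened	oversweet
overly sweetened	oversweet
heavily sweetened	oversweet
overpoweringly sweet	oversweet
overwhelmingly sweet	oversweet
sickeningly sweet	oversweet
sickly sweet	oversweet
cloyingly sweet	oversweet
cloying sweet	oversweet
disgustingly sweet	oversweet
nauseatingly sweet	oversweet
unbearably sweet	oversweet
insanely sweet	oversweet
ridiculously sweet	oversweet
crazy sweet	oversweet
absurdly sweet	oversweet
excessively sweet	oversweet
extremely sweet	oversweet
terribly sweet	oversweet
horribly sweet	oversweet
painfully sweet	oversweet
achingly sweet	oversweet
intensely sweet	oversweet
syrupy sweet	oversweet
sugary sweet	oversweet
super sweet	oversweet
too much sweetness	oversweet
way too much sweetness	oversweet
excessive sweetness	oversweet
overpowering sweetness	oversweet
overwhelming sweetness	oversweet
cloying sweetness	oversweet
sickening sweetness	oversweet
unbearable sweetness	oversweet
sweeter than i like	oversweet
sweeter than i prefer	oversweet
sweeter than expected	oversweet
sweeter than necessary	oversweet
too sweet to drink	oversweet
too sweet to eat	oversweet
too sweet to finish	oversweet
not sweet	under-sweet
not sweet at all	under-sweet
not nearly sweet enough	under-sweet
not as sweet as expected	under-sweet
barely sweet	under-sweet
hardly sweet	under-sweet
scarcely sweet	under-sweet
barely any sweetness	under-sweet
hardly any sweetness	under-sweet
no sweetness	under-sweet
no sweetness at all	under-sweet
lacks sweetness	under-sweet
lacking sweetness	under-sweet
lacked sweetness	under-sweet
needs more sweetness	under-sweet
needed more sweetness	under-sweet
could be sweeter	under-sweet
could use more sweetness	under-sweet
wish it was sweeter	under-sweet
wish it were sweeter	under-sweet
under sweetened	under-sweet
undersweetened	under-sweet
very sweet	neutral
quite sweet	neutral
pretty sweet	neutral
fairly sweet	neutral
slightly sweet	neutral
lightly sweet	neutral
mildly sweet	neutral
a little sweet	neutral
a bit sweet	neutral
a touch sweet	neutral
somewhat sweet	neutral
perfectly sweet	neutral
nicely sweet	neutral
pleasantly sweet	neutral
naturally sweet	neutral
delicately sweet	neutral
subtly sweet	neutral
gently sweet	neutral
sweet enough	neutral
just sweet enough	neutral
just the right sweetness	neutral
perfect amount of sweetness	neutral
right amount of sweetness	neutral
perfect sweetness	neutral
nice sweetness	neutral
pleasant sweetness	neutral
mild sweetness	neutral
subtle sweetness	neutral
light sweetness	neutral
gentle sweetness	neutral
hint of sweetness	neutral
touch of sweetness	neutral
sweet taste	neutral
sweet flavor	neutral
sweet flavour	neutral
sweet aroma	neutral
sweet smell	neutral
sweet and salty	neutral
sweet and sour	neutral
sweet and tangy	neutral
semi sweet	neutral
semisweet	neutral
bittersweet	neutral
slightly sweetened	neutral
lightly sweetened	neutral
mildly sweetened	neutral
sweetener	excluded
sweeteners	excluded
sweet tooth	excluded
sweet leaf	excluded
sweet potato	excluded
sweet potatoes	excluded
sweet pea	excluded
sweet peas	excluded
sweet corn	excluded
sweet cream	excluded
sweet chili	excluded
sweet onion	excluded
sweetheart	excluded
sweethearts	excluded
sweetie	excluded
sweet spot	excluded
sweet deal	excluded
home sweet home	excluded
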