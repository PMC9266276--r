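# Filler words removed from raw ingredient strings before tokenization.
ingredients
ingredient
contains
contain
containing
includes
including
with
and
or
of
in
the
a
an
from
may
made
following
less
than
percent
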