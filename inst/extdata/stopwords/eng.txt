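# English stop words
the
a
an
of
in
on
for
and
or
with
without
at
by
from
to
is
are
this
that
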