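# common English function words removed after emphasis counting;
# boosters/negators/contrast markers are protected from removal in code
a
an
the
and
or
if
then
this
that
these
those
i
me
my
mine
we
us
our
you
your
he
him
his
she
her
it
its
they
them
their
what
which
who
whom
is
am
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
to
of
in
on
at
by
for
with
about
into
through
during
before
after
above
below
from
up
down
out
off
over
under
again
further
here
there
when
where
why
how
all
any
each
few
more
most
other
some
such
only
own
same
than
too
just
now
as
until
while
will
would
can
could
shall
should
may
might
must
im
ive
id
youre
theres
gonna
got
get
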