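the
a
an
and
for
with
to
in
on
at
is
was
are
has
had
have
he
she
they
patient
seen
today
review
reviewed
feels
feeling
well
better
worse
settled
improved
stable
normal
abnormal
denies
no
not
nil
without
possible
probable
suspected
likely
query
history
previous
ago
year
years
month
months
week
weeks
day
days
but
however
letter
from
hospital
scanned
document
clinic
attended
attends
refer
referred
came
visit
visited
old
man
woman
admitted
discharged
home
since
still
now
this
that
complains
reports
states
walked
walking
advice
given
plan
continue
monitor
one
two
three
four
five
six
seven
eight
nine
ten
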