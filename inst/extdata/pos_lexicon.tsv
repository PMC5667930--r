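# token<TAB>coarse tag {noun,verb,adjective,adverb,preposition,other}
hookah	noun
hookahs	noun
hooka	noun
shisha	noun
sheesha	noun
sesh	noun
lounge	noun
bar	noun
flavor	noun
flavors	noun
smoke	verb
smoking	verb
smoked	verb
vibe	noun
night	noun
tonight	adverb
today	adverb
later	adverb
friends	noun
friend	noun
crew	noun
spot	noun
place	noun
music	noun
weekend	noun
coals	noun
coal	noun
pipe	noun
bowl	noun
mint	noun
grape	noun
apple	noun
lemon	noun
feeling	verb
feel	verb
love	verb
hate	verb
enjoy	verb
trying	verb
tried	verb
want	verb
need	verb
go	verb
going	verb
went	verb
chilling	verb
hanging	verb
picked	verb
heading	verb
tastes	verb
smells	verb
deal	noun
sale	noun
battery	noun
happy	adjective
great	adjective
good	adjective
amazing	adjective
awesome	adjective
wonderful	adjective
excellent	adjective
fantastic	adjective
lovely	adjective
perfect	adjective
nice	adjective
relaxing	adjective
tasty	adjective
delicious	adjective
sweet	adjective
fresh	adjective
horrible	adjective
terrible	adjective
awful	adjective
bad	adjective
nasty	adjective
disgusting	adjective
gross	adjective
sad	adjective
boring	adjective
stale	adjective
harsh	adjective
smelly	adjective
new	adjective
old	adjective
excited	adjective
calm	adjective
relaxed	adjective
stressed	adjective
bored	adjective
tired	adjective
downtown	adverb
again	adverb
always	adverb
never	adverb
really	adverb
very	adverb
soon	adverb
in	preposition
on	preposition
at	preposition
with	preposition
from	preposition
to	preposition
of	preposition
for	preposition
by	preposition
about	preposition
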