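# token<TAB>valence in [-4, 4]
wonderful	2.7
horrible	-2.5
happy	2.7
great	3.1
good	1.9
amazing	2.8
awesome	3.1
excellent	2.7
fantastic	2.6
fabulous	2.4
love	3.2
like	1.5
best	3.2
fun	2.3
enjoy	2.2
beautiful	2.9
lovely	2.8
perfect	2.7
nice	1.8
cool	1.3
relaxing	1.8
smooth	1.3
tasty	1.9
delicious	2.3
sweet	1.8
glad	2.0
joy	2.9
excited	2.4
thrilled	2.9
pumped	1.9
blessed	2.9
win	2.4
fresh	1.3
friendly	2.2
favorite	2.0
dope	1.6
paradise	2.9
heaven	2.6
laugh	2.2
smile	1.7
satisfying	2.0
comfortable	1.7
cozy	1.9
bliss	2.7
epic	2.4
magical	2.5
stellar	2.6
superb	2.9
outstanding	3.0
incredible	2.8
pleasant	2.3
calm	1.3
serene	1.9
peaceful	2.1
mellow	1.2
chill	1.1
thanks	1.9
terrible	-2.1
awful	-2.0
bad	-2.5
worst	-3.1
hate	-2.7
nasty	-2.6
disgusting	-2.4
gross	-1.9
sad	-2.1
unhappy	-1.8
depressed	-2.3
angry	-2.3
mad	-2.2
annoying	-1.8
boring	-1.3
bored	-1.1
tired	-0.8
sick	-1.5
sucks	-1.5
stupid	-2.4
dumb	-2.3
ugly	-2.2
pain	-1.9
hurt	-1.7
crap	-2.0
trash	-1.9
garbage	-1.9
ruined	-2.0
broken	-1.6
dirty	-1.4
smelly	-1.6
stink	-1.8
harsh	-1.3
bitter	-1.3
weak	-1.1
disappointing	-2.0
fail	-2.0
worse	-2.1
problem	-1.3
scary	-1.6
afraid	-1.9
fear	-1.7
nervous	-1.3
stressed	-1.8
tense	-1.2
upset	-1.9
unpleasant	-2.1
miserable	-2.7
gloomy	-1.6
lonely	-1.8
cry	-1.9
wrong	-1.4
headache	-1.6
cough	-1.1
toxic	-2.0
poison	-2.4
danger	-2.0
risky	-1.3
regret	-1.9
SMILE	2.0
FROWN	-1.8
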