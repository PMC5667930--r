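# token<TAB>arousal in [-1, 1] (activation positive, deactivation negative)
excited	0.80
thrilled	0.80
pumped	0.85
hyped	0.80
active	0.70
alert	0.60
energetic	0.75
wild	0.70
party	0.60
crazy	0.65
intense	0.70
angry	0.70
furious	0.85
mad	0.60
stressed	0.65
tense	0.60
nervous	0.55
anxious	0.60
panic	0.80
scared	0.60
upset	0.45
annoying	0.40
elated	0.60
epic	0.50
calm	-0.65
relaxing	-0.60
relaxed	-0.60
serene	-0.70
peaceful	-0.65
mellow	-0.55
chill	-0.50
cozy	-0.45
quiet	-0.50
sleepy	-0.80
tired	-0.70
bored	-0.50
boring	-0.45
lazy	-0.55
subdued	-0.60
gloomy	-0.35
depressed	-0.45
sad	-0.30
smooth	-0.30
comfortable	-0.35
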