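# a valence word within 3 tokens after one of these has its sign flipped
not
no
never
none
nothing
nobody
neither
nor
hardly
barely
scarcely
isnt
arent
wasnt
werent
dont
doesnt
didnt
cant
cannot
couldnt
wont
wouldnt
shouldnt
aint
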