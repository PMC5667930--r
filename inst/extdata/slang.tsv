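# slang/misspelling corrections applied during normalization
luv	love
gr8	great
awsome	awesome
gud	good
rly	really
sux	sucks
fab	fabulous
thx	thanks
plz	please
b4	before
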