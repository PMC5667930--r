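# known spam phrases used by the bot spam feature (normalized-token match)
follow me
click here
free followers
check my bio
dm for promo
win a free
limited offer
make money fast
follow back
hot singles
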