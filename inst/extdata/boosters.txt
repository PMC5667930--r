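# degree modifiers: a valence word immediately after one of these is counted twice
very
extremely
really
so
incredibly
absolutely
totally
super
insanely
especially
particularly
remarkably
utterly
truly
highly
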