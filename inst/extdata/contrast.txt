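# contrast markers: tokens after the (last) marker get weight 1.5, before 0.5
but
however
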