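# Tokens after which a period never ends a sentence (trailing dot omitted).
Fig
al
e.g
i.e
vs
Dr
ca
approx
no
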