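# Drug dictionary: canonical_id<TAB>surface_form.
# Generic name, salt, brand names, chemical synonyms and the ambiguous
# shorthand "MET" (also a gene symbol; flagged by harmonize_lexicons).
metformin	metformin
metformin	metformin hydrochloride
metformin	Glucophage
metformin	Glumetza
metformin	Fortamet
metformin	Riomet
metformin	Diabex
metformin	Diaformin
metformin	Glifage
metformin	Siofor
metformin	dimethylbiguanide
metformin	1,1-dimethylbiguanide
metformin	N,N-dimethylimidodicarbonimidic diamide
metformin	MET
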