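cue	class	direction
activate	interaction	none
activates	interaction	none
activated	interaction	none
activation	interaction	none
inhibit	interaction	decreased
inhibits	interaction	decreased
inhibited	interaction	decreased
transport	interaction	none
transports	interaction	none
transported	interaction	none
increase	interaction	increased
increases	interaction	increased
increased	interaction	increased
decrease	interaction	decreased
decreases	interaction	decreased
decreased	interaction	decreased
reduce	interaction	decreased
reduces	interaction	decreased
reduced	interaction	decreased
suppress	interaction	decreased
suppresses	interaction	decreased
suppressed	interaction	decreased
lower	interaction	decreased
lowers	interaction	decreased
lowered	interaction	decreased
enhance	interaction	increased
enhances	interaction	increased
enhanced	interaction	increased
elevate	interaction	increased
elevates	interaction	increased
elevated	interaction	increased
affect	interaction	none
affects	interaction	none
affected	interaction	none
regulate	interaction	none
regulates	interaction	none
regulated	interaction	none
induce	interaction	none
induces	interaction	none
induced	interaction	none
alter	interaction	none
alters	interaction	none
altered	interaction	none
influence	interaction	none
influences	interaction	none
influenced	interaction	none
stimulate	interaction	none
stimulates	interaction	none
stimulated	interaction	none
modulate	interaction	none
modulates	interaction	none
modulated	interaction	none
mediate	interaction	none
mediates	interaction	none
mediated	interaction	none
not	negation	none
never	negation	none
no	negation	none
neither	negation	none
nor	negation	none
lack	negation	none
lacks	negation	none
lacked	negation	none
absence	negation	none
without	negation	none
may	hedge	none
might	hedge	none
could	hedge	none
possibly	hedge	none
possible	hedge	none
hypothesis	hedge	none
hypothesised	hedge	none
hypothesized	hedge	none
hypothetical	hedge	none
suggest	hedge	none
suggests	hedge	none
suggested	hedge	none
suggesting	hedge	none
potentially	hedge	none
unclear	hedge	none
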