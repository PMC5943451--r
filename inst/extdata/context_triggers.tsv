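pattern	category	max_scope
no	negation_pre	5
not	negation_pre	5
never	negation_pre	5
denies	negation_pre	5
denied	negation_pre	5
deny	negation_pre	5
denying	negation_pre	5
without	negation_pre	5
didn't	negation_pre	5
doesn't	negation_pre	5
cannot	negation_pre	5
ruled out	negation_pre	5
was ruled out	negation_post	5
unlikely	negation_post	5
history of	historical	200
past	historical	200
previous	historical	200
previously	historical	200
former	historical	200
if	hypothetical	200
whether	hypothetical	200
in case	hypothetical	200
mother	experiencer	200
father	experiencer	200
brother	experiencer	200
sister	experiencer	200
husband	experiencer	200
wife	experiencer	200
son	experiencer	200
daughter	experiencer	200
aunt	experiencer	200
uncle	experiencer	200
friend	experiencer	200
family	experiencer	200
but	termination	1
however	termination	1
although	termination	1
though	termination	1
apart from	termination	1
aside from	termination	1
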