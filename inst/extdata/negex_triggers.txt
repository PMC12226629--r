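# Negation trigger lexicon, seeded with the standard NegEx trigger set and
# a few phrases common in UK ultrasound reporting. One trigger per line:
# phrase<TAB>TAG, tags PRE (pre-negation), POST (post-negation), PSEUDO
# (looks like a trigger but never negates), TERM (scope terminator),
# UNC (hypothetical/uncertainty; flags but never suppresses a match).
absence of	PRE
cannot see	PRE
denied	PRE
denies	PRE
free of	PRE
negative for	PRE
never had	PRE
no	PRE
no abnormal	PRE
no evidence of	PRE
no new	PRE
no sign of	PRE
no signs of	PRE
no suspicious	PRE
not	PRE
rather than	PRE
rules out	PRE
unable to see	PRE
without	PRE
absent	POST
excluded	POST
free	POST
not appreciated	POST
not demonstrated	POST
not identified	POST
not observed	POST
not present	POST
not seen	POST
not visualised	POST
not visualized	POST
resolved	POST
ruled out	POST
gram negative	PSEUDO
no change	PSEUDO
no further	PSEUDO
no increase	PSEUDO
no interval change	PSEUDO
not cause	PSEUDO
not certain	PSEUDO
not only	PSEUDO
although	TERM
apart from	TERM
aside from	TERM
but	TERM
cause for	TERM
cause of	TERM
causes of	TERM
except	TERM
however	TERM
reason for	TERM
secondary to	TERM
likely	UNC
may represent	UNC
perhaps	UNC
possible	UNC
possibly	UNC
probable	UNC
query	UNC
questionable	UNC
suspected	UNC
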