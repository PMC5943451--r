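rule_id	field	pattern	category
heading_title	context_string	(?m)^[ \t]*(?:[A-Za-z0-9][).][ \t]*)?(?:history of[ \t]+)?(?:previous[ \t]+|past[ \t]+)?suicid(?:e|al)[ \t]+attempts?[ \t]*(?:/[ \t]*ideation)?[ \t]*(?:x+|\*+)?[ \t]*$	title_neutral
questionnaire_item	context_string	\b(?:have|has|did|do|does)[ \t]+(?:you|he|she|they)[ \t]+ever\b[^?\n]{0,80}\battempt	title_neutral
ambiguous_previously_also	context_string	\bpreviously[ \t]+also[ \t]+attempted[ \t]+to\b	ambiguous
ambiguous_dangling_attempt	context_string	\battempted[ \t]+to[ \t]*$	ambiguous
negation_pre_match	context_string	\b(?:no|not|never|nil|without|den(?:y|ies|ied|ying)|didn|doesn|wouldn|couldn|cannot|unable)\b	negation_before_match
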