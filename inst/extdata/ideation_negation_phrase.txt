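# Phrase-scope negation cues for the rule-based ideation classifier.
would not
didn't
does not
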