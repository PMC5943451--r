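# Sentence-scope negation cues for the rule-based ideation classifier.
# Any match in the mention's sentence vetoes the ideation mention.
no
not
nil
denie*
denied
without
never
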