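# Seed dictionary of suicide-attempt terms (wildcards allowed). This is a
# replacement lexicon built from commonly recorded attempt phrasings; supply
# your own file to adapt it to local recording habits.
suicide attempt*
suicidal attempt*
attempted suicide
attempt* suicide
attempt* to end her life
attempt* to end his life
attempt* to kill himself
attempt* to kill herself
attempt* to take her life
attempt* to take his life
overdose*
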