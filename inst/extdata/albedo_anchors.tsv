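state	average	minimum	maximum
dry_clean	0.90	0.95	0.85
wet_clean	0.75	0.80	0.70
red	0.65	0.77	0.53
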