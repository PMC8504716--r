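arm,events,no_events
C,194,2139
T,269,4418
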