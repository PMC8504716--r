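{"a": 194, "b": 269, "c": 2139, "d": 4418}
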