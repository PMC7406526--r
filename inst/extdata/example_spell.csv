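zebra,zebru
elephant,african elephant
elephant,asian elephant
wolf,woolf
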