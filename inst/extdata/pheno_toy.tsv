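id	value
ind1	10.4
ind2	9.1
ind3	12.3
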