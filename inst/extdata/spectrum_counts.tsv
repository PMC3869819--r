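class	count
GC>AT	428
AT>GC	2
AT>CG	1
indel	1
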