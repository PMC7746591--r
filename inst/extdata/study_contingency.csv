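metastasis,low_group,high_group
Yes,0,18
No,11,9
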