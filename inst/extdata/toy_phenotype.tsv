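sample_id	condition
sample1	tumor
sample2	normal
sample3	tumor
sample4	normal
sample5	tumor
sample6	normal
sample7	tumor
sample8	normal
sample9	tumor
sample10	normal
sample11	tumor
sample12	normal
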