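time_ns,n_CM15,n_SUR,count
110,4,4,1
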