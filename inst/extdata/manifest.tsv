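file	md5
table1.tsv	de96f0cf28f7107f2f5a0fc7e8f2586b
table2.tsv	9992c34c2957018d731d0b373e0bb4a6
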