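chr6	0	59800000
chr16	36800000	90338345
chrX	0	156040895
chr1	121700000	125100000
chr9	38000000	61000000
chr16	35300000	36800000
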