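>madcam1_ce_synthetic constructed promoter composite element; two COUP-TFII half-sites (GGTCR matches, minus strand) separated by a 7-nt gap, with an NKX homeodomain site
GCTTAAGTGCATTTGACCAATTATCTGACCCTTCAGGA
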