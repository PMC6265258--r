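>sibirica synthetic 61-nt nad4 amplicon stand-in, diagnostic site 31 (allele T)
TATCAAATAACCAGGGCGAAGAGCGGGTAGTTCTATACATAAGTCTTGCCATCTTTGGCAT
>gmelinii synthetic 61-nt nad4 amplicon stand-in, diagnostic site 31 (allele C)
TATCAAATAACCAGGGCGAAGAGCGGGTAGCTCTATACATAAGTCTTGCCATCTTTGGCAT
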