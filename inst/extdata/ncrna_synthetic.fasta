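>ncrna_synthetic_1 synthetic test ncRNA (not a biological sequence)
GGCUGCUAAAGCUGCAGGAUCCUUAGCAGCC
>ncrna_synthetic_2 synthetic test ncRNA (not a biological sequence)
ACCUCCUUAGCAGCCAUGGUAGCUCAGUUGGU
>ncrna_synthetic_3 synthetic test ncRNA (not a biological sequence)
GGUUCGAAUCCUUCCGGAUGCACCA
>ncrna_synthetic_4 synthetic test ncRNA (not a biological sequence)
UGCCUGGCGGCCGUAGCGCGGUGGUCCCACCU
>ncrna_synthetic_5 synthetic test ncRNA (not a biological sequence)
AAGUGAAAGCUUGCAUGCCUGCAGGUCGACUCUAG
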