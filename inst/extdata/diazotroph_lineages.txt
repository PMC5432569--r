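# Curated lineage patterns for taxa with known diazotrophic (nitrogen-fixing)
# members. Matched case-insensitively against taxon lineages at any rank.
# Edit freely: this list is curated, not canonical.
Burkholderiales
Rhizobiales
Rhodospirillales
Nostocales
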