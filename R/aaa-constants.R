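# Shared constants; this file must collate before everything else.

TAXONOMIC_RANKS <- c("realm", "kingdom", "phylum", "class", "order",
                     "family", "genus")

GENOME_TYPES <- c("dsDNA", "ssDNA", "dsRNA", "ssRNA", "mixed-DNA", "unknown")

BASES <- c("A", "C", "G", "T")
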