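#!/usr/bin/env Rscript
# Read-level analyses for the sequenced representative sites: de-noising
# quality filter (300 bp / mean Q25 / homopolymer <= 6 / primer + barcode),
# demultiplexing, analytic rarefaction and coverage per sample, OTU sharing
# across sites, diazotroph screening, and the nifH tally worked example.

library(hypolithr)

reads <- read_fastq("results/bundle/reads.fastq")
bc <- read.delim("results/bundle/barcodes.tsv")
barcode_map <- setNames(bc$barcode, bc$sample_id)

verdicts <- qc_filter_reads(reads, primer = "CCTACGGGAGGCAGCAG",
                            barcode_map = barcode_map)
cat(sprintf("QC: %d of %d reads pass (%.1f%%)\n", sum(verdicts$passed),
            nrow(reads), 100 * mean(verdicts$passed)))
fail <- table(unlist(strsplit(verdicts$reasons[!verdicts$passed], ",")))
for (r in names(fail)) cat(sprintf("  failed %-12s %d\n", r, fail[[r]]))

dmx <- demultiplex(reads[verdicts$passed, ], barcode_map)
cat("Demultiplexed reads/sample:",
    paste(sprintf("%s=%d", names(dmx$by_sample),
                  vapply(dmx$by_sample, nrow, integer(1))), collapse = ", "),
    sprintf("(unmatched %d)\n", nrow(dmx$unmatched)))

# Per-sample taxon count vectors from the generator's read origins (ground
# truth stands in for the out-of-scope 97% OTU clustering step).
truth <- read.delim("results/bundle/read_truth.tsv")
truth <- truth[truth$id %in% unlist(lapply(dmx$by_sample, `[[`, "id")), ]
otu_counts <- lapply(split(truth$taxon, truth$sample_id), table)

cat("\nAnalytic rarefaction (expected taxa at half depth; coverage):\n")
rar <- lapply(names(otu_counts), function(s) {
  counts <- as.integer(otu_counts[[s]])
  N <- sum(counts)
  d <- round(N / 2)
  data.frame(sample_id = s, depth = d,
             expected_richness = rarefaction_expected_richness(counts, d),
             coverage = coverage_at_depth(counts, d))
})
rar <- do.call(rbind, rar)
print(rar, row.names = FALSE)
write.table(rar, "results/rarefaction.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

venn <- shared_otu_counts(lapply(otu_counts, names))
shared_all <- venn$count[venn$n_samples == length(otu_counts)]
cat("\nOTU sharing:", if (length(shared_all)) shared_all else 0,
    "taxa found in all", length(otu_counts), "sequenced sites\n")
write.table(venn, "results/otu_sharing.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

refs <- read_taxonomy("results/bundle/taxonomy.tsv")
cat("\nPutative diazotroph relative abundance per sequenced site:\n")
for (s in names(otu_counts)) {
  ab <- as.numeric(otu_counts[[s]]) / sum(otu_counts[[s]])
  names(ab) <- refs$lineage[match(names(otu_counts[[s]]), refs$id)]
  cat(sprintf("  %s: %.1f%%\n", s,
              100 * screen_diazotrophs(ab, default_diazotroph_list())))
}

tally <- tally_nifh_otus(read_nifh_table())
cat("\nnifH tally: most abundant OTU", tally$by_otu$otu[1], "with",
    tally$by_otu$total[1], "reads (", tally$by_otu$order[1], ");",
    "grand total", tally$grand_total, "reads\n")
write.table(tally$by_order, "results/nifh_by_order.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
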