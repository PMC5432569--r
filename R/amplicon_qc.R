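#' Longest homopolymer run in a sequence
#' @param seq DNA string; empty input returns 0.
#' @return Integer length of the longest single-character run.
#' @export
max_homopolymer_run <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) return(0L)
  max(rle(strsplit(seq, "")[[1]])$lengths)
}

#' De-noising quality filter for pyrosequencing reads
#'
#' A read fails if it meets any of the stated removal criteria: shorter than
#' `min_len` (length of the untrimmed read, barcode and primer in place);
#' mean per-base phred quality below `min_avg_q`; any ambiguous (non-ACGT)
#' base outside the barcode region; a homopolymer run longer than `max_hp`;
#' missing primer; or missing barcode. All reasons are evaluated — the
#' verdict lists every criterion the read meets, not just the first.
#'
#' @param sequence Read sequence (may contain IUPAC ambiguity codes).
#' @param qualities Integer phred scores, one per base.
#' @param min_len Minimum read length in bp (default 300).
#' @param min_avg_q Minimum arithmetic-mean phred score (default 25).
#' @param max_hp Maximum tolerated homopolymer run length (default 6; a run
#'   of more than 6 identical bases fails).
#' @param primer Primer sequence the read must contain (IUPAC, matched with
#'   `max_mismatch` mismatches).
#' @param barcode_map Named character vector, sample id -> barcode; the read
#'   must start with one of the barcodes.
#' @param max_mismatch Mismatches tolerated in the primer search (default 0).
#' @return List with `passed` (logical) and `reasons` (character vector,
#'   subset of too_short, low_quality, ambiguous, homopolymer, no_primer,
#'   no_barcode; empty iff passed).
#' @export
qc_filter <- function(sequence, qualities, min_len = 300, min_avg_q = 25,
                      max_hp = 6, primer, barcode_map, max_mismatch = 0L) {
  stopifnot(min_len > 0, min_avg_q > 0, max_hp > 0)
  reasons <- character(0)
  if (nchar(sequence) < min_len) reasons <- c(reasons, "too_short")
  if (mean(qualities) < min_avg_q) reasons <- c(reasons, "low_quality")
  bc_len <- 0L
  bc_hit <- vapply(barcode_map,
                   function(b) startsWith(sequence, b), logical(1))
  if (any(bc_hit)) bc_len <- nchar(barcode_map[which(bc_hit)[1]])
  body <- substring(sequence, bc_len + 1L)
  if (grepl("[^ACGT]", body)) reasons <- c(reasons, "ambiguous")
  if (max_homopolymer_run(sequence) > max_hp) {
    reasons <- c(reasons, "homopolymer")
  }
  if (is.na(find_primer(sequence, primer, max_mismatch))) {
    reasons <- c(reasons, "no_primer")
  }
  if (!any(bc_hit)) reasons <- c(reasons, "no_barcode")
  list(passed = length(reasons) == 0L, reasons = reasons)
}

#' Apply the quality filter to a set of reads
#'
#' @param reads Data frame from [read_fastq()].
#' @inheritParams qc_filter
#' @return Data frame with columns `id`, `passed`, `reasons` (comma-joined).
#' @export
qc_filter_reads <- function(reads, primer, barcode_map, min_len = 300,
                            min_avg_q = 25, max_hp = 6, max_mismatch = 0L) {
  verdicts <- mapply(function(s, q) {
    qc_filter(s, q, min_len, min_avg_q, max_hp, primer, barcode_map,
              max_mismatch)
  }, reads$sequence, reads$qualities, SIMPLIFY = FALSE)
  data.frame(
    id = reads$id,
    passed = vapply(verdicts, `[[`, logical(1), "passed"),
    reasons = vapply(verdicts, function(v) paste(v$reasons, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

#' Demultiplex reads by exact 5' barcode prefix
#'
#' Barcodes must be mutually non-prefixing so that every read matches at most
#' one sample; reads matching no barcode are returned separately.
#'
#' @param reads Data frame from [read_fastq()].
#' @param barcode_map Named character vector, sample id -> barcode.
#' @return List with `by_sample` (named list of read data frames) and
#'   `unmatched` (read data frame).
#' @export
demultiplex <- function(reads, barcode_map) {
  bcs <- unname(barcode_map)
  for (i in seq_along(bcs)) {
    for (j in seq_along(bcs)) {
      if (i != j && startsWith(bcs[j], bcs[i])) {
        stop("ambiguous barcode table: '", bcs[i], "' is a prefix of '",
             bcs[j], "'")
      }
    }
  }
  assigned <- rep(NA_character_, nrow(reads))
  for (s in names(barcode_map)) {
    hit <- is.na(assigned) & startsWith(reads$sequence, barcode_map[[s]])
    assigned[hit] <- s
  }
  by_sample <- lapply(names(barcode_map), function(s) {
    reads[which(assigned == s), , drop = FALSE]
  })
  names(by_sample) <- names(barcode_map)
  list(by_sample = by_sample,
       unmatched = reads[is.na(assigned), , drop = FALSE])
}

#' Analytic rarefaction: expected OTU richness at a subsampling depth
#'
#' Hypergeometric expectation of the number of OTUs observed in a random
#' subsample of `depth` reads drawn without replacement:
#' `E[S(depth)] = sum_i (1 - choose(N - N_i, depth) / choose(N, depth))`.
#'
#' @param counts Non-negative integer OTU count vector.
#' @param depth Subsampling depth, `0 <= depth <= sum(counts)`.
#' @return Expected richness (numeric).
#' @export
rarefaction_expected_richness <- function(counts, depth) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (depth < 0 || depth > N) stop("depth must lie in [0, total reads]")
  if (depth == 0) return(0)
  # lchoose is stable where choose() overflows at these depths
  p_absent <- exp(lchoose(N - counts, depth) - lchoose(N, depth))
  sum(1 - p_absent)
}

#' Fraction of observed richness recovered at a subsampling depth
#'
#' `E[S(depth)] / S`, the expected share of the observed OTUs a rarefied
#' sample of the given depth would capture; monotone non-decreasing in depth.
#'
#' @inheritParams rarefaction_expected_richness
#' @return Fraction in `[0, 1]`.
#' @export
coverage_at_depth <- function(counts, depth) {
  S <- sum(counts > 0)
  if (S == 0) stop("no observed OTUs")
  rarefaction_expected_richness(counts, depth) / S
}

#' Shared-OTU counts for every intersection region
#'
#' Tallies the OTU universe into the non-empty membership patterns of a Venn
#' diagram: for each subset of samples, the number of OTUs found in exactly
#' those samples. Region counts partition the universe.
#'
#' @param otu_sets Named list (>= 2) of character vectors of OTU ids.
#' @return Data frame with columns `pattern` (`&`-joined sample names),
#'   `n_samples`, `count`.
#' @export
shared_otu_counts <- function(otu_sets) {
  if (length(otu_sets) < 2L) stop("need at least 2 sets")
  universe <- unique(unlist(otu_sets, use.names = FALSE))
  membership <- vapply(otu_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(m) {
    paste(names(otu_sets)[m], collapse = "&")
  })
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab),
                    n_samples = lengths(strsplit(names(tab), "&", fixed = TRUE)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$n_samples, out$pattern), , drop = FALSE]
}

#' Default diazotroph screening list
#'
#' A curated (not canonical) list of lineage patterns for taxa with known
#' nitrogen-fixing members: the proteobacterial orders Burkholderiales,
#' Rhizobiales and Rhodospirillales, plus the cyanobacterial order
#' Nostocales. Shipped as an editable plain-text config.
#'
#' @return Character vector of lineage patterns.
#' @export
default_diazotroph_list <- function() {
  path <- system.file("extdata", "diazotroph_lineages.txt",
                      package = "hypolithr")
  lines <- readLines(path)
  lines <- trimws(lines[!startsWith(trimws(lines), "#")])
  lines[nzchar(lines)]
}

#' Screen taxon abundances for putative diazotrophs
#'
#' Sums the relative abundance of taxa whose lineage matches any pattern in
#' the diazotroph list (fixed-string, case-insensitive matching at any rank).
#'
#' @param taxon_abundances Numeric vector of relative abundances, named by
#'   lineage (or any string the patterns are matched against).
#' @param diazotroph_list Character vector of lineage patterns; must be
#'   supplied explicitly (see [default_diazotroph_list()]).
#' @return Summed relative abundance of matching taxa, in `[0, 1]`.
#' @export
screen_diazotrophs <- function(taxon_abundances, diazotroph_list) {
  if (length(diazotroph_list) == 0L) {
    stop("diazotroph list is empty; supply lineage patterns explicitly")
  }
  hit <- vapply(names(taxon_abundances), function(lin) {
    any(vapply(diazotroph_list,
               function(p) grepl(p, lin, ignore.case = TRUE, fixed = FALSE),
               logical(1)))
  }, logical(1))
  sum(taxon_abundances[hit])
}

#' Tally a nifH OTU count table by OTU and taxonomic order
#'
#' @param otu_table Data frame with column `otu` (id), one numeric column per
#'   site, and column `order` (taxonomic order label).
#' @return List with `by_otu` (input plus a `total` column, sorted by
#'   descending total), `by_order` (data frame `order`, `total`) and
#'   `grand_total`.
#' @export
tally_nifh_otus <- function(otu_table) {
  site_cols <- setdiff(names(otu_table), c("otu", "order"))
  counts <- as.matrix(otu_table[, site_cols, drop = FALSE])
  if (any(counts < 0)) stop("negative counts")
  by_otu <- otu_table
  by_otu$total <- rowSums(counts)
  by_otu <- by_otu[order(-by_otu$total), , drop = FALSE]
  ord_tot <- tapply(by_otu$total, by_otu$order, sum)
  by_order <- data.frame(order = names(ord_tot),
                         total = as.numeric(ord_tot),
                         stringsAsFactors = FALSE)
  by_order <- by_order[order(-by_order$total), , drop = FALSE]
  list(by_otu = by_otu, by_order = by_order, grand_total = sum(counts))
}
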