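# Independent oracles used throughout the suite. These deliberately take a
# different route from the package implementation: regex-engine scans with
# lookahead for motif positions, naive agglomeration for UPGMA, plain loops
# for run lengths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# IUPAC code -> regex character class
iupac_regex <- function(pattern) {
  classes <- c(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(classes[strsplit(pattern, "")[[1]]], collapse = "")
}

# all (overlapping) start positions of an IUPAC motif, via regex lookahead
oracle_motif_starts <- function(seq, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

oracle_cut_positions <- function(seq, recognition, cut_offset) {
  sort(oracle_motif_starts(seq, recognition) - 1L + cut_offset)
}

# leftmost exact-match (0 mismatches) primer position via regex
oracle_find_primer <- function(seq, primer) {
  m <- regexpr(iupac_regex(primer), seq, perl = TRUE)
  if (m == -1) NA_integer_ else as.integer(m)
}

# longest run by explicit loop
oracle_max_run <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  best <- 0L; cur <- 0L; prev <- ""
  for (ch in chars) {
    cur <- if (ch == prev) cur + 1L else 1L
    prev <- ch
    if (cur > best) best <- cur
  }
  best
}

# naive UPGMA agglomeration: merge clusters while the smallest average
# pairwise dissimilarity is <= cutoff; returns partition labelled by first
# member order
oracle_upgma_groups <- function(D, cutoff) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- mean(D[clusters[[i]], clusters[[j]]])
          if (d < best_d) { best_d <- d; best <- c(i, j) }
        }
      }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  for (g in seq_along(clusters)) labels[clusters[[g]]] <- g
  # renumber by first member
  match(labels, unique(labels))
}

# partition equality up to label names
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# tiny profile constructor for community tests
make_profile <- function(sizes, abundances, sample_id = "s") {
  out <- data.frame(representative_bp = sizes, abundance = abundances)
  attr(out, "sample_id") <- sample_id
  out
}

# assignment data frame straight from role masses (for P/C unit tests)
make_assignment <- function(abundance, role,
                            assigned = !is.na(role) | FALSE) {
  data.frame(representative_bp = seq_along(abundance),
             abundance = abundance,
             taxon_id = ifelse(is.na(role), NA, paste0("t", seq_along(role))),
             role = role,
             assigned = !is.na(role),
             ambiguous = FALSE, stringsAsFactors = FALSE)
}
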