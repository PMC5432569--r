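PRIMER <- "CCTACGGGAGGCAGCAG"
BC_MAP <- c(sampleA = "ACGTACGT", sampleB = "TTGGCCAA")

# a read passing every filter: barcode + primer + clean body
clean_read <- function(body_len = 330, bc = BC_MAP[["sampleA"]]) {
  body <- paste(rep(c("A", "C", "G", "T"), length.out = body_len),
                collapse = "")
  paste0(bc, PRIMER, body)
}

test_that("longest homopolymer run matches a loop oracle", {
  expect_equal(max_homopolymer_run("AAAT"), 3L)
  expect_equal(max_homopolymer_run("ACGT"), 1L)
  expect_equal(max_homopolymer_run(""), 0L)
  set.seed(51)
  for (rep in 1:30) {
    s <- random_dna(200)
    expect_equal(max_homopolymer_run(s), oracle_max_run(s))
  }
})

test_that("the read filter applies every stated de-noising criterion", {
  s <- clean_read()
  q <- rep(30L, nchar(s))
  v <- qc_filter(s, q, primer = PRIMER, barcode_map = BC_MAP)
  expect_true(v$passed)
  expect_length(v$reasons, 0L)

  # 299 bp, otherwise clean
  s299 <- substr(clean_read(), 1, 299)
  v299 <- qc_filter(s299, rep(30L, 299), primer = PRIMER, barcode_map = BC_MAP)
  expect_equal(v299$reasons, "too_short")

  # mean quality just below 25
  vq <- qc_filter(s, rep(24L, nchar(s)), primer = PRIMER, barcode_map = BC_MAP)
  expect_equal(vq$reasons, "low_quality")

  # homopolymer: run of 7 fails, run of 6 passes
  s7 <- paste0(clean_read(), "GGGGGGG")
  expect_equal(qc_filter(s7, rep(30L, nchar(s7)), primer = PRIMER,
                         barcode_map = BC_MAP)$reasons, "homopolymer")
  s6 <- paste0(clean_read(), "TGGGGGGT")
  expect_true(qc_filter(s6, rep(30L, nchar(s6)), primer = PRIMER,
                        barcode_map = BC_MAP)$passed)

  # ambiguous base outside the barcode region
  sN <- paste0(clean_read(), "N")
  expect_equal(qc_filter(sN, rep(30L, nchar(sN)), primer = PRIMER,
                         barcode_map = BC_MAP)$reasons, "ambiguous")

  # primer and barcode absence
  no_p <- paste0(BC_MAP[["sampleA"]],
                 paste(rep("AC", 160), collapse = ""))
  expect_equal(qc_filter(no_p, rep(30L, nchar(no_p)), primer = PRIMER,
                         barcode_map = BC_MAP)$reasons, "no_primer")
  no_b <- paste0("GGGGTTTT", PRIMER,
                 paste(rep("AC", 160), collapse = ""))
  expect_equal(qc_filter(no_b, rep(30L, nchar(no_b)), primer = PRIMER,
                         barcode_map = BC_MAP)$reasons, "no_barcode")
})

test_that("all failure reasons are reported, not just the first", {
  s <- substr(clean_read(), 1, 200)        # short
  s <- sub(substr(PRIMER, 1, 17), "NANANANANANANANAN", s)  # kills primer, adds N
  v <- qc_filter(s, rep(10L, nchar(s)), primer = PRIMER, barcode_map = BC_MAP)
  expect_false(v$passed)
  expect_setequal(v$reasons,
                  c("too_short", "low_quality", "ambiguous", "no_primer"))
})

test_that("demultiplexing routes by exact barcode prefix and rejects prefixing tables", {
  reads <- data.frame(
    id = c("r1", "r2", "r3"),
    sequence = c(paste0(BC_MAP[["sampleA"]], "AAAA"),
                 paste0(BC_MAP[["sampleB"]], "CCCC"),
                 "GGGGGGGGGGGG"),
    qualities = I(replicate(3, rep(30L, 12), simplify = FALSE)),
    stringsAsFactors = FALSE)
  dmx <- demultiplex(reads, BC_MAP)
  expect_equal(dmx$by_sample$sampleA$id, "r1")
  expect_equal(dmx$by_sample$sampleB$id, "r2")
  expect_equal(dmx$unmatched$id, "r3")
  expect_error(demultiplex(reads, c(a = "ACGT", b = "ACGTAC")), "prefix")
})

test_that("simulated reads with intact barcodes demultiplex to their true origin", {
  cfg <- sim_config(seed = 52, n_sites = 4, n_seq_sites = 2, n_reads = 500,
                    defect_rate = 0)
  b <- simulate_study(cfg)
  dmx <- demultiplex(b$reads, b$barcode_map)
  expect_equal(nrow(dmx$unmatched), 0L)
  for (s in names(dmx$by_sample)) {
    truth <- b$read_truth$sample_id[match(dmx$by_sample[[s]]$id,
                                          b$read_truth$id)]
    expect_true(all(truth == s))
  }
})

test_that("analytic rarefaction has the right endpoints and matches resampling", {
  counts <- c(10, 5, 3, 1, 1)
  N <- sum(counts)
  expect_equal(rarefaction_expected_richness(counts, N), 5)
  expect_equal(rarefaction_expected_richness(counts, 1), 1)
  expect_equal(rarefaction_expected_richness(counts, 0), 0)
  expect_error(rarefaction_expected_richness(counts, N + 1), "depth")

  set.seed(53)
  labels <- rep(seq_along(counts), counts)
  depth <- 10
  mc <- replicate(5000, length(unique(labels[sample.int(N, depth)])))
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(rarefaction_expected_richness(counts, depth) - mean(mc)),
            3 * se)
})

test_that("expected richness is monotone and concave in depth; coverage is a fraction", {
  set.seed(54)
  for (rep in 1:5) {
    counts <- rpois(20, 15) + 1
    N <- sum(counts)
    es <- vapply(0:N, function(d) rarefaction_expected_richness(counts, d),
                 numeric(1))
    expect_true(all(diff(es) >= -1e-10))
    expect_true(all(diff(diff(es)) <= 1e-10))
    cov <- vapply(c(0, round(N / 2), N), function(d)
      coverage_at_depth(counts, d), numeric(1))
    expect_equal(cov[1], 0)
    expect_equal(cov[3], 1)
    expect_true(cov[2] >= 0 && cov[2] <= 1)
  }
  expect_error(coverage_at_depth(c(0, 0), 0), "no observed")
})

test_that("Venn region counts partition the OTU universe", {
  out <- shared_otu_counts(list(X = c("a", "b"), Y = c("b", "c")))
  expect_equal(out$count[out$pattern == "X&Y"], 1L)
  expect_equal(out$count[out$pattern == "X"], 1L)
  expect_equal(out$count[out$pattern == "Y"], 1L)
  ident <- shared_otu_counts(list(p = c("a", "b"), q = c("a", "b")))
  expect_equal(ident$pattern, "p&q")
  expect_equal(ident$count, 2L)
  set.seed(55)
  universe <- paste0("otu", 1:60)
  sets <- lapply(1:4, function(i) sample(universe, sample(10:40, 1)))
  names(sets) <- LETTERS[1:4]
  out4 <- shared_otu_counts(sets)
  expect_equal(sum(out4$count), length(unique(unlist(sets))))
  # brute-force membership enumeration oracle
  for (k in seq_len(nrow(out4))) {
    members <- strsplit(out4$pattern[k], "&", fixed = TRUE)[[1]]
    inside <- Reduce(intersect, sets[members])
    outside <- unique(unlist(sets[setdiff(names(sets), members)]))
    expect_equal(out4$count[k], length(setdiff(inside, outside)))
  }
})

test_that("diazotroph screening sums matching lineage mass", {
  ab <- c("Proteobacteria;Alphaproteobacteria;Rhizobiales;x;Rhizobium" = 0.053,
          "Cyanobacteria;Cyanophyceae;Oscillatoriales;x;Phormidium" = 0.70,
          "Actinobacteria;x;Actinomycetales;x;Arthrobacter" = 0.247)
  expect_equal(screen_diazotrophs(ab, default_diazotroph_list()), 0.053)
  expect_equal(screen_diazotrophs(ab, "Nostocales"), 0)
  expect_error(screen_diazotrophs(ab, character(0)), "empty")
  # generator ground truth: planted diazotroph mass recovered exactly
  cfg <- sim_config(seed = 56, n_sites = 2)
  b <- simulate_study(cfg, with_reads = FALSE)
  ab2 <- setNames(b$true_abundances[, 1], b$refs$lineage)
  expect_equal(screen_diazotrophs(ab2, default_diazotroph_list()),
               sum(b$true_abundances[b$refs$diazotroph, 1]))
})

test_that("nifH tallies reproduce row, order and grand totals", {
  tab <- read_nifh_table()
  tally <- tally_nifh_otus(tab)
  expect_equal(tally$by_otu$total[1], 23)
  expect_equal(tally$by_otu$otu[1], 1)
  expect_equal(tally$by_order$total[tally$by_order$order == "Rhizobiales"], 29)
  expect_equal(tally$grand_total, 63)
  # random tables: totals equal brute-force sums
  set.seed(57)
  rt <- data.frame(otu = 1:6, s1 = rpois(6, 3), s2 = rpois(6, 3),
                   s3 = rpois(6, 3), order = sample(c("X", "Y"), 6, TRUE))
  t2 <- tally_nifh_otus(rt)
  expect_equal(sort(t2$by_otu$total),
               sort(rt$s1 + rt$s2 + rt$s3))
  expect_equal(t2$grand_total, sum(rt$s1, rt$s2, rt$s3))
  rt$s1[1] <- -1
  expect_error(tally_nifh_otus(rt), "negative")
  # all-zero row has total 0
  rt0 <- data.frame(otu = 1, s1 = 0, s2 = 0, order = "X")
  expect_equal(tally_nifh_otus(rt0)$by_otu$total, 0)
})
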