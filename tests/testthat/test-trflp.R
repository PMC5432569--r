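pt <- function(sizes, heights, areas = heights, mean = 0, sd = 10,
               id = "s1") {
  peak_table(id, data.frame(size_bp = sizes, height = heights, area = areas),
             mean, sd)
}

test_that("noise filtering excludes peaks at or below mean + k*SD and is idempotent", {
  tab <- pt(c(100, 200), c(25, 31))
  out <- filter_noise(tab, k = 3)
  expect_equal(out$peaks$height, 31)
  # the boundary itself (exactly 3 SD above baseline) is excluded
  expect_equal(nrow(filter_noise(pt(100, 30))$peaks), 0L)
  # idempotent; output is a subset of input
  expect_identical(filter_noise(out, 3), out)
  empty <- pt(numeric(0), numeric(0))
  expect_equal(nrow(filter_noise(empty)$peaks), 0L)
  expect_error(filter_noise(pt(100, 50), k = 0), "k")
  expect_error(peak_table("s", data.frame(size_bp = 1, height = 1, area = 1),
                          0, -1), "noise_sd")
})

test_that("peaks within 1 bp merge by single linkage; chains are allowed", {
  bins <- bin_peaks(pt(c(100.4, 101.2, 150.0), c(100, 100, 100)))
  expect_equal(nrow(bins), 2L)
  expect_equal(bins$n_members, c(2L, 1L))
  # adjacent gaps <= 1 chain into a single bin even when the span exceeds 1
  chain <- bin_peaks(pt(c(100.0, 100.9, 101.8), c(1, 1, 1)))
  expect_equal(nrow(chain), 1L)
  single <- bin_peaks(pt(123.4, 500))
  expect_equal(single$representative_bp, 123.4)
})

test_that("bin representatives are area-weighted means inside the member range", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    sizes <- sort(runif(n, 50, 500))
    areas <- runif(n, 10, 1000)
    tab <- pt(sizes, areas, areas)
    bins <- bin_peaks(tab)
    # partition: every peak in exactly one bin
    expect_equal(sum(bins$n_members), n)
    expect_equal(sum(bins$total_area), sum(areas))
    for (b in seq_len(nrow(bins))) {
      members <- abs(sizes - bins$representative_bp[b]) <= 2  # loose window
      expect_true(bins$representative_bp[b] >= min(sizes) &&
                    bins$representative_bp[b] <= max(sizes))
    }
    # representative of a two-peak bin equals the direct weighted mean
  }
  two <- bin_peaks(pt(c(100, 100.8), c(1, 1), c(30, 10)))
  expect_equal(two$representative_bp, (100 * 30 + 100.8 * 10) / 40)
})

test_that("relative abundances are area ratios that sum to one", {
  bins <- bin_peaks(pt(c(100, 200, 300), c(1, 1, 1), c(50, 30, 20)))
  prof <- relative_abundance(bins)
  expect_equal(prof$abundance, c(0.5, 0.3, 0.2))
  expect_equal(relative_abundance(bin_peaks(pt(100, 1, 42)))$abundance, 1)
  set.seed(32)
  for (rep in 1:10) {
    areas <- runif(8, 1, 100)
    prof <- relative_abundance(bin_peaks(pt(seq(50, 400, 50), rep(1, 8), areas)))
    expect_equal(sum(prof$abundance), 1, tolerance = 1e-9)
    expect_equal(prof$abundance, areas / sum(areas))
  }
  expect_error(relative_abundance(bin_peaks(pt(numeric(0), numeric(0)))),
               "no bins")
})

test_that("bins assign to the nearest predicted fragment within 1 bp", {
  dig <- data.frame(id = c("p1", "c1"), trf_bp = c(205.0, 300.0),
                    role = c("producer", "consumer"), stringsAsFactors = FALSE)
  prof <- make_profile(c(204.6, 250.0), c(0.6, 0.4))
  asg <- assign_bins(prof, dig)
  expect_true(asg$assigned[1])
  expect_equal(asg$taxon_id[1], "p1")
  expect_false(asg$assigned[2])   # nothing within [249, 251]
  # equidistant tie across roles: ambiguous, role withheld
  dig2 <- data.frame(id = c("p1", "c1"), trf_bp = c(204.1, 205.1),
                     role = c("producer", "consumer"), stringsAsFactors = FALSE)
  asg2 <- assign_bins(make_profile(204.6, 1), dig2)
  expect_true(asg2$ambiguous)
  expect_true(is.na(asg2$role))
  # tie among taxa sharing a role keeps the role
  dig3 <- data.frame(id = c("p1", "p2"), trf_bp = c(204.1, 205.1),
                     role = c("producer", "producer"), stringsAsFactors = FALSE)
  asg3 <- assign_bins(make_profile(204.6, 1), dig3)
  expect_true(asg3$ambiguous)
  expect_equal(asg3$role, "producer")
  expect_error(assign_bins(prof, dig[0, ]), "empty")
})

test_that("producer/consumer ratio is the producer-to-consumer abundance mass ratio", {
  # division of printed community abundances: 68.7% producers, 31.3% consumers
  asg <- make_assignment(c(0.687, 0.313), c("producer", "consumer"))
  pc <- producer_consumer_ratio(asg)
  expect_equal(pc$pc, 0.687 / 0.313, tolerance = 1e-12)
  expect_equal(pc$pc, 2.195, tolerance = 1e-3)
  expect_equal(pc$producer_fraction, 0.687)
  # symmetry
  expect_equal(producer_consumer_ratio(
    make_assignment(c(0.5, 0.5), c("producer", "consumer")))$pc, 1)
  # degenerate: no consumers -> flagged infinite
  pc_inf <- producer_consumer_ratio(make_assignment(1, "producer"))
  expect_true(is.infinite(pc_inf$pc))
  expect_true(pc_inf$infinite)
  expect_error(producer_consumer_ratio(make_assignment(1, NA_character_)),
               "no role")
  # unassigned mass is excluded and reported
  asg2 <- make_assignment(c(0.4, 0.4, 0.2),
                          c("producer", "consumer", NA_character_))
  pc2 <- producer_consumer_ratio(asg2)
  expect_equal(pc2$pc, 1)
  expect_equal(pc2$excluded_mass, 0.2)
})

test_that("assignment rate counts assigned bins over all bins", {
  asg <- make_assignment(rep(1 / 89, 89),
                         c(rep("producer", 73), rep(NA_character_, 16)))
  expect_equal(assignment_rate(asg), 73 / 89)
  expect_equal(assignment_rate(make_assignment(1, "producer")), 1)
  expect_equal(assignment_rate(make_assignment(c(1, 1), rep(NA_character_, 2))), 0)
})

test_that("end-to-end peak processing recovers the generating taxa", {
  # size-call noise well below the 1-bp tolerance, true fragments 5 bp apart
  cfg <- sim_config(seed = 77, n_sites = 20, size_call_sd = 0.15)
  b <- simulate_study(cfg, with_reads = FALSE)
  dig <- virtual_digest(b$refs)
  acc <- unlist(lapply(b$peak_tables, function(ptab) {
    s <- process_sample(ptab, dig$table)
    a <- s$assignment
    truth <- b$digest_truth$id[
      vapply(a$representative_bp,
             function(bp) which.min(abs(b$digest_truth$trf_bp - bp)),
             integer(1))]
    a$assigned & a$taxon_id == truth
  }))
  expect_gte(mean(acc), 0.95)
})
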