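test_that("Bray-Curtis matches the formula, its bounds and a vegan oracle", {
  expect_equal(bray_curtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  skip_if_not_installed("vegan")
  set.seed(41)
  for (rep in 1:20) {
    m <- matrix(runif(12), 2, 6)
    expect_equal(bray_curtis(m[1, ], m[2, ]),
                 as.numeric(vegan::vegdist(m, method = "bray")),
                 tolerance = 1e-12)
  }
})

test_that("dissimilarity matrix is symmetric with zero diagonal and matches pairwise values", {
  profs <- list(a = make_profile(c(100, 200), c(0.5, 0.5)),
                b = make_profile(c(100, 200), c(0.5, 0.5)),
                c = make_profile(c(100, 300), c(0.2, 0.8)))
  D <- dissimilarity_matrix(profs)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 3), names(profs)))
  expect_equal(D["a", "b"], 0)
  # against the direct pairwise computation on the aligned table
  mat <- align_profiles(profs)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(D[i, j], bray_curtis(mat[i, ], mat[j, ]))
  }
  expect_error(dissimilarity_matrix(profs[1]), "at least 2")
})

test_that("cross-sample alignment merges representatives within 1 bp", {
  profs <- list(a = make_profile(c(100.0, 200.0), c(0.5, 0.5)),
                b = make_profile(c(100.6, 200.3), c(0.4, 0.6)))
  mat <- align_profiles(profs)
  expect_equal(ncol(mat), 2L)     # 100.0/100.6 and 200.0/200.3 share bins
  expect_equal(unname(rowSums(mat)), c(1, 1))
  expect_equal(dissimilarity_matrix(profs)["a", "b"],
               1 - 2 * (0.4 + 0.5) / 2)
})

test_that("grouping cuts the UPGMA tree at the dissimilarity cutoff", {
  D <- matrix(0.9, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(D) <- 0
  D["A", "B"] <- D["B", "A"] <- 0.1
  g <- cluster_groups(D, 0.40)
  expect_equal(g[["A"]], g[["B"]])
  expect_false(g[["A"]] == g[["C"]])
  all_far <- matrix(0.9, 4, 4); diag(all_far) <- 0
  dimnames(all_far) <- list(letters[1:4], letters[1:4])
  expect_equal(length(unique(cluster_groups(all_far, 0.40))), 4L)
})

test_that("grouping equals a naive UPGMA agglomeration oracle on random matrices", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 5
    d <- matrix(0, n, n)
    d[lower.tri(d)] <- runif(n * (n - 1) / 2)
    D <- d + t(d)
    dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
    got <- cluster_groups(D, 0.40)
    want <- oracle_upgma_groups(D, 0.40)
    expect_true(same_partition(unname(got), want))
  }
})

test_that("NMDS reaches near-zero stress on an exactly embeddable configuration", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  D <- as.matrix(dist(X))
  fit <- nmds(D, k = 2, n_starts = 5, seed = 9)
  expect_lt(fit$stress, 0.01)
  # accepted stress values never increase
  expect_true(all(diff(fit$stress_history) <= 1e-12))
})

test_that("stress is invariant under rotation and reflection of the configuration", {
  set.seed(43)
  X <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(matrix(rnorm(12), 6, 2)))
  s0 <- kruskal_stress(D, X)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(kruskal_stress(D, X %*% R), s0, tolerance = 1e-10)
  expect_equal(kruskal_stress(D, X %*% diag(c(-1, 1))), s0, tolerance = 1e-10)
})

test_that("NMDS stress is no worse than the classical metric MDS configuration", {
  set.seed(44)
  for (rep in 1:5) {
    d <- matrix(0, 6, 6)
    d[lower.tri(d)] <- runif(15, 0.1, 1)
    D <- d + t(d)
    fit <- nmds(D, k = 2, n_starts = 5, seed = 100 + rep)
    cmd <- cmdscale(as.dist(D), k = 2)
    expect_lte(fit$stress, kruskal_stress(D, cmd) + 1e-12)
  }
})

test_that("a degenerate all-equal dissimilarity matrix warns and flags non-convergence", {
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  expect_warning(fit <- nmds(D, k = 2, n_starts = 2, seed = 5), "equal")
  expect_false(fit$converged)
  expect_true(is.matrix(fit$points))
})

test_that("order-of-magnitude P/C outliers are excluded with leave-one-out means", {
  pc <- setNames(c(30, 2, 2, 2, 3, 3), paste0("s", 1:6))
  loc <- c("hot", "hot", "hot", "hot", "polar", "polar")
  out <- remove_pc_outliers(pc, loc)
  expect_equal(out$excluded, "s1")
  expect_equal(length(out$retained), 5L)
  # a merely high value is retained
  pc2 <- setNames(c(5, 2, 2, 2, 3, 3), paste0("s", 1:6))
  expect_equal(length(remove_pc_outliers(pc2, loc)$excluded), 0L)
  # all-equal values: nothing excluded
  pc3 <- setNames(rep(2, 5), paste0("s", 1:5))
  expect_equal(length(remove_pc_outliers(pc3, rep("x", 5))$excluded), 0L)
})

test_that("the climate regression matches the closed-form least-squares oracle", {
  md <- data.frame(site_id = paste0("s", 1:5), koppen = "BWh",
                   map_mm = c(10, 50, 80, 120, 200), tmin_c = 0, tmax_c = 30,
                   growing_season_d = c(0, 20, 40, 60, 90))
  pc <- setNames(c(2.4, 2.1, 1.4, 1.1, 0.6), md$site_id)
  fit <- fit_pc_vs_climate(pc, md, "growing_season_d")
  x <- md$growing_season_d; y <- unname(pc)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(fit$r_squared, fit$r^2, tolerance = 1e-12)
  expect_equal(fit$signed_r_squared, sign(fit$r) * fit$r^2)
  expect_lt(fit$p_value, 0.05)
  # collinear points: perfect fit
  pc_lin <- setNames(2 - 0.01 * x, md$site_id)
  # suppress lm's "essentially perfect fit" note on the exact-fit input
  fit_lin <- suppressWarnings(fit_pc_vs_climate(pc_lin, md, "growing_season_d"))
  expect_equal(fit_lin$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit_lin$p_value, 1e-10)
  # degenerate predictor
  md0 <- md; md0$tmin_c <- 5
  expect_error(fit_pc_vs_climate(pc, md0, "tmin_c"), "variance")
})
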