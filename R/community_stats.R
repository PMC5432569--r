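#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `d = 1 - 2 * sum(min(a_i, b_i)) / (sum(a) + sum(b))`: 0 for identical
#' profiles, 1 for disjoint supports.
#'
#' @param a,b Non-negative abundance vectors over the same bin universe.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(a, b)) / (sa + sb)
}

#' Align community profiles onto a shared bin universe
#'
#' Fragment bins from different samples are re-binned jointly with the same
#' single-linkage 1-bp rule used within samples: all representatives are
#' pooled, sorted, and adjacent representatives with gap <= `tol_bp` merge
#' into one cross-sample bin.
#'
#' @param profiles Named list of profiles from [relative_abundance()].
#' @param tol_bp Merge tolerance in bp.
#' @return Numeric matrix, samples x shared bins; column names are the
#'   abundance-weighted mean sizes of the shared bins.
#' @export
align_profiles <- function(profiles, tol_bp = 1.0) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("profiles must be a named list")
  }
  sizes <- unlist(lapply(profiles, `[[`, "representative_bp"), use.names = FALSE)
  ab <- unlist(lapply(profiles, `[[`, "abundance"), use.names = FALSE)
  sample <- rep(names(profiles), vapply(profiles, nrow, integer(1)))
  ord <- order(sizes)
  sizes <- sizes[ord]; ab <- ab[ord]; sample <- sample[ord]
  bin <- cumsum(c(TRUE, diff(sizes) > tol_bp))
  rep_bp <- as.numeric(tapply(sizes * ab, bin, sum) / tapply(ab, bin, sum))
  mat <- matrix(0, nrow = length(profiles), ncol = max(bin),
                dimnames = list(names(profiles), sprintf("%.2f", rep_bp)))
  for (i in seq_along(sizes)) {
    mat[sample[i], bin[i]] <- mat[sample[i], bin[i]] + ab[i]
  }
  mat
}

#' Bray-Curtis dissimilarity matrix across samples
#'
#' @param profiles Named list of profiles from [relative_abundance()].
#' @param tol_bp Cross-sample bin alignment tolerance.
#' @return Symmetric matrix with zero diagonal.
#' @export
dissimilarity_matrix <- function(profiles, tol_bp = 1.0) {
  if (length(profiles) < 2L) stop("need at least 2 samples")
  mat <- align_profiles(profiles, tol_bp)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- bray_curtis(mat[i, ], mat[j, ])
    }
  }
  D
}

#' Group communities by a dissimilarity cutoff
#'
#' Group-average (UPGMA) hierarchical clustering of the dissimilarity matrix,
#' cut at the given height — the convention behind "groups at a 40%
#' dissimilarity cutoff". Group labels are integers numbered in order of each
#' group's first member.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param cutoff Tree cut height (default 0.40).
#' @return Named integer vector of group labels.
#' @export
cluster_groups <- function(D, cutoff = 0.40) {
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  raw <- stats::cutree(hc, h = cutoff)
  stats::setNames(match(raw, unique(raw)), names(raw))
}

#' Kruskal stress-1 of a configuration
#'
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`, where `d` are configuration
#' distances and `dhat` the disparities obtained by monotone
#' (pool-adjacent-violators) regression of `d` on the rank order of the
#' input dissimilarities (primary approach to ties).
#'
#' @param D Dissimilarity matrix.
#' @param X Configuration matrix (n x k).
#' @return Stress-1 value (>= 0).
#' @export
kruskal_stress <- function(D, X) {
  dd <- as.vector(stats::as.dist(D))
  d <- as.vector(stats::dist(X))
  if (sum(d^2) == 0) return(1)
  ord <- order(dd, d)
  dhat <- numeric(length(d))
  dhat[ord] <- stats::isoreg(seq_along(ord), d[ord])$yf
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

# One monotone-regression/Guttman-transform pass with step halving so the
# accepted stress sequence never increases.
.nmds_one_start <- function(D, X, max_iter, tol) {
  n <- nrow(X)
  dd <- as.vector(stats::as.dist(D))
  stress <- kruskal_stress(D, X)
  history <- stress
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- as.matrix(stats::dist(X))
    dv <- as.vector(stats::as.dist(d))
    ord <- order(dd, dv)
    dhat_v <- numeric(length(dv))
    dhat_v[ord] <- stats::isoreg(seq_along(ord), dv[ord])$yf
    dhat <- matrix(0, n, n)
    dhat[lower.tri(dhat)] <- dhat_v
    dhat <- dhat + t(dhat)
    ratio <- ifelse(d > 0, dhat / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    prop <- (B %*% X) / n
    s_new <- kruskal_stress(D, prop)
    step <- 1
    while (s_new > stress && step > 1 / 64) {      # only accept non-increasing stress
      step <- step / 2
      prop <- X + step * ((B %*% X) / n - X)
      s_new <- kruskal_stress(D, prop)
    }
    if (s_new > stress) { converged <- TRUE; break }
    improved <- stress - s_new
    X <- scale(prop, center = TRUE, scale = FALSE)
    stress <- s_new
    history <- c(history, stress)
    if (improved < tol) { converged <- TRUE; break }
  }
  list(X = X, stress = stress, history = history, converged = converged)
}

#' Non-metric multidimensional scaling (Kruskal stress-1)
#'
#' Minimises Kruskal stress-1 by alternating pool-adjacent-violators monotone
#' regression of configuration distances on dissimilarity ranks with
#' Guttman-transform coordinate updates (step-halved so accepted stress is
#' non-increasing). The first start is the classical metric MDS
#' configuration; the remaining starts are random. The best configuration
#' over all starts is returned.
#'
#' @param D Symmetric dissimilarity matrix, `n >= k + 1`.
#' @param k Embedding dimension (default 2).
#' @param n_starts Number of starts including the metric-MDS start.
#' @param max_iter Iterations per start.
#' @param tol Stress-improvement convergence tolerance.
#' @param seed Integer seed; required for reproducibility.
#' @return List with `points` (n x k), `stress`, `stress_history` (accepted
#'   stress values of the winning start), `converged`, `n_starts`, `seed`.
#' @export
nmds <- function(D, k = 2, n_starts = 20, max_iter = 300, tol = 1e-6, seed) {
  if (missing(seed)) stop("seed is required")
  n <- nrow(D)
  if (n < k + 1) stop("need at least k + 1 samples")
  offdiag <- as.vector(stats::as.dist(D))
  degenerate <- length(unique(round(offdiag, 12))) == 1L
  if (degenerate) {
    warning("all dissimilarities are equal; NMDS configuration is arbitrary")
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    X0 <- if (s == 1L) {
      cmd <- stats::cmdscale(stats::as.dist(D), k = k)
      if (ncol(cmd) < k) cbind(cmd, matrix(0, n, k - ncol(cmd))) else cmd
    } else {
      matrix(stats::rnorm(n * k, sd = stats::sd(offdiag) + 0.1), n, k)
    }
    fit <- .nmds_one_start(D, X0, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  rownames(best$X) <- rownames(D)
  list(points = best$X, stress = best$stress, stress_history = best$history,
       converged = !degenerate && best$converged, n_starts = n_starts,
       seed = seed)
}

#' Flag extreme producer/consumer outliers
#'
#' A sample is excluded when its P/C value exceeds both the mean of its own
#' location and the mean of the overall dataset by an order of magnitude
#' (>= `factor` times each), with both means computed without the candidate.
#'
#' @param pc_values Named numeric vector of P/C values (names = sample ids).
#' @param site_labels Location label per sample (same order).
#' @param factor Order-of-magnitude factor (default 10).
#' @return List with `retained` (named numeric vector) and `excluded`
#'   (character vector of sample ids).
#' @export
remove_pc_outliers <- function(pc_values, site_labels, factor = 10) {
  if (length(pc_values) < 2L) stop("need at least 2 samples")
  if (length(site_labels) != length(pc_values)) {
    stop("site_labels must match pc_values in length")
  }
  out <- vapply(seq_along(pc_values), function(i) {
    loc <- site_labels == site_labels[i]
    loc[i] <- FALSE
    loc_mean <- if (any(loc)) mean(pc_values[loc]) else NA_real_
    overall_mean <- mean(pc_values[-i])
    !is.na(loc_mean) && loc_mean > 0 && overall_mean > 0 &&
      pc_values[i] >= factor * loc_mean && pc_values[i] >= factor * overall_mean
  }, logical(1))
  list(retained = pc_values[!out],
       excluded = names(pc_values)[out] %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simple linear regression of P/C on a climate predictor
#'
#' Ordinary least squares of the (untransformed, by default) P/C value on one
#' of the macroclimate predictors. Reports the slope, intercept, Pearson r,
#' r-squared, the signed r-squared (`sign(r) * r^2`, the convention in which
#' a negative value encodes an inverse relationship), and a two-sided p-value
#' for the slope from the t distribution on n - 2 degrees of freedom.
#'
#' @param pc_values Named numeric vector of P/C values (names = site ids in
#'   `metadata$site_id`).
#' @param metadata Data frame from [read_metadata()].
#' @param predictor One of `"growing_season_d"`, `"map_mm"`, `"tmin_c"`,
#'   `"tmax_c"`.
#' @param log_pc Regress `log(P/C)` instead of P/C (default `FALSE`).
#' @param excluded Character vector of already-excluded sample ids, recorded
#'   in the result.
#' @return List with `slope`, `intercept`, `r`, `r_squared`,
#'   `signed_r_squared`, `p_value`, `n`, `predictor`, `excluded`.
#' @export
fit_pc_vs_climate <- function(pc_values, metadata,
                              predictor = c("growing_season_d", "map_mm",
                                            "tmin_c", "tmax_c"),
                              log_pc = FALSE, excluded = character(0)) {
  predictor <- match.arg(predictor)
  idx <- match(names(pc_values), metadata$site_id)
  if (anyNA(idx)) {
    stop("no metadata for sample(s): ",
         paste(names(pc_values)[is.na(idx)], collapse = ", "))
  }
  x <- metadata[[predictor]][idx]
  y <- if (log_pc) log(pc_values) else pc_values
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- as.numeric(y[keep])
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r <- stats::cor(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, r_squared = r^2, signed_r_squared = sign(r) * r^2,
       p_value = sm$coefficients[2, 4],
       n = length(x), predictor = predictor, excluded = excluded)
}
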