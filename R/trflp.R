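#' Build a per-sample peak table
#'
#' @param sample_id Sample identifier.
#' @param peaks Data frame with columns `size_bp` (>0), `height` (>=0),
#'   `area` (>0).
#' @param noise_mean,noise_sd Baseline-noise statistics of the
#'   electropherogram, in signal units; `noise_sd` must be >= 0.
#' @return A `peak_table` list.
#' @export
peak_table <- function(sample_id, peaks, noise_mean, noise_sd) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (nrow(peaks)) {
    stopifnot(all(peaks$size_bp > 0), all(peaks$height >= 0),
              all(peaks$area > 0))
  }
  structure(list(sample_id = sample_id,
                 peaks = peaks[, c("size_bp", "height", "area")],
                 noise_mean = noise_mean, noise_sd = noise_sd),
            class = "peak_table")
}

#' Read peak tables from a PeakScanner-style CSV plus a noise sidecar
#'
#' @param peaks_csv CSV with columns `sample_id`, `size_bp`, `height`, `area`.
#' @param noise_tsv TSV with columns `sample_id`, `noise_mean`, `noise_sd`.
#' @return Named list of `peak_table` objects, one per sample.
#' @export
read_peak_tables <- function(peaks_csv, noise_tsv) {
  pk <- utils::read.csv(peaks_csv, stringsAsFactors = FALSE)
  nz <- utils::read.delim(noise_tsv, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing <- setdiff(unique(pk$sample_id), nz$sample_id)
  if (length(missing)) {
    stop("no noise statistics for sample(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(nz$sample_id, function(s) {
    peak_table(s, pk[pk$sample_id == s, , drop = FALSE],
               nz$noise_mean[nz$sample_id == s],
               nz$noise_sd[nz$sample_id == s])
  })
  names(out) <- nz$sample_id
  out
}

#' Exclude peaks within k standard deviations of the baseline noise
#'
#' A peak is retained iff its height exceeds `noise_mean + k * noise_sd`;
#' peaks at or below the threshold are excluded (the boundary itself is
#' excluded). Idempotent.
#'
#' @param table A `peak_table`.
#' @param k Number of noise standard deviations (default 3).
#' @return The filtered `peak_table`.
#' @export
filter_noise <- function(table, k = 3) {
  if (k <= 0) stop("k must be > 0")
  if (table$noise_sd < 0) stop("noise_sd must be >= 0")
  thr <- table$noise_mean + k * table$noise_sd
  table$peaks <- table$peaks[table$peaks$height > thr, , drop = FALSE]
  table
}

#' Bin fragments of similar size
#'
#' Greedy single-linkage over sizes sorted ascending: adjacent peaks whose
#' gap is at most `tol_bp` join the same bin, so peaks within 1 bp of one
#' another are treated as the same taxon. A chain of near peaks can span more
#' than `tol_bp` in total. The bin representative is the area-weighted mean
#' size of its members.
#'
#' @param table A noise-filtered `peak_table`.
#' @param tol_bp Adjacent-gap tolerance in bp (default 1.0).
#' @return Data frame with columns `representative_bp`, `n_members`,
#'   `total_area`.
#' @export
bin_peaks <- function(table, tol_bp = 1.0) {
  pk <- table$peaks
  if (nrow(pk) == 0L) {
    return(data.frame(representative_bp = numeric(), n_members = integer(),
                      total_area = numeric()))
  }
  ord <- order(pk$size_bp)
  sz <- pk$size_bp[ord]; ar <- pk$area[ord]
  new_bin <- c(TRUE, diff(sz) > tol_bp)
  bin_id <- cumsum(new_bin)
  rep_bp <- as.numeric(tapply(sz * ar, bin_id, sum) / tapply(ar, bin_id, sum))
  data.frame(representative_bp = rep_bp,
             n_members = as.integer(tapply(sz, bin_id, length)),
             total_area = as.numeric(tapply(ar, bin_id, sum)))
}

#' Relative abundance profile from fragment bins
#'
#' Relative abundance of each fragment is the ratio of its (binned) peak area
#' to the total area of all peaks; abundances sum to 1.
#'
#' @param bins Data frame from [bin_peaks()] with at least one bin.
#' @param sample_id Optional sample identifier attached to the profile.
#' @return Data frame with columns `representative_bp`, `abundance`; the
#'   sample id is stored in attribute `"sample_id"`.
#' @export
relative_abundance <- function(bins, sample_id = NULL) {
  if (nrow(bins) == 0L) stop("no bins: cannot form a profile")
  total <- sum(bins$total_area)
  if (total <= 0) stop("zero total area")
  out <- data.frame(representative_bp = bins$representative_bp,
                    abundance = bins$total_area / total)
  attr(out, "sample_id") <- sample_id
  out
}

#' Assign fragment bins to reference taxa via predicted TRF sizes
#'
#' Each bin is matched to the nearest predicted terminal restriction fragment
#' within `tol_bp`. Ties — equal distance to two fragment sizes, or several
#' taxa sharing one predicted size — are flagged ambiguous; the trophic role
#' is still assigned when all tied taxa share it, otherwise left unset. Bins
#' with no fragment within tolerance stay unassigned.
#'
#' @param profile Data frame from [relative_abundance()].
#' @param digest_table Data frame with columns `id`, `trf_bp`, `role`
#'   (from [virtual_digest()]).
#' @param tol_bp Assignment tolerance in bp (default 1.0).
#' @return Data frame with columns `representative_bp`, `abundance`,
#'   `taxon_id` (comma-joined if tied), `role`, `assigned`, `ambiguous`.
#' @export
assign_bins <- function(profile, digest_table, tol_bp = 1.0) {
  if (nrow(digest_table) == 0L) stop("empty digest table")
  res <- lapply(profile$representative_bp, function(bp) {
    d <- abs(digest_table$trf_bp - bp)
    dmin <- min(d)
    if (dmin > tol_bp) {
      return(list(taxon_id = NA_character_, role = NA_character_,
                  assigned = FALSE, ambiguous = FALSE))
    }
    hit <- which(d == dmin)
    roles <- unique(digest_table$role[hit])
    list(taxon_id = paste(digest_table$id[hit], collapse = ","),
         role = if (length(roles) == 1L) roles else NA_character_,
         assigned = TRUE, ambiguous = length(hit) > 1L)
  })
  data.frame(representative_bp = profile$representative_bp,
             abundance = profile$abundance,
             taxon_id = vapply(res, `[[`, character(1), "taxon_id"),
             role = vapply(res, `[[`, character(1), "role"),
             assigned = vapply(res, `[[`, logical(1), "assigned"),
             ambiguous = vapply(res, `[[`, logical(1), "ambiguous"),
             stringsAsFactors = FALSE)
}

#' Producer/consumer ratio of a community
#'
#' P is the summed relative abundance of producer bins (autotrophs:
#' Cyanobacteria and chemoautotrophs), C that of consumer bins (all other
#' bacteria); P/C is their ratio. Bins that are unassigned or whose tied
#' assignment spans both roles contribute to neither sum; their mass is
#' reported as `excluded_mass`. When C = 0 the ratio is flagged infinite.
#'
#' @param assignment Data frame from [assign_bins()].
#' @return List with `pc` (ratio; `Inf` when C = 0), `producer_fraction`
#'   (P / (P + C)), `p_mass`, `c_mass`, `excluded_mass`, `infinite` flag.
#' @export
producer_consumer_ratio <- function(assignment) {
  role <- assignment$role
  p_mass <- sum(assignment$abundance[!is.na(role) & role == "producer"])
  c_mass <- sum(assignment$abundance[!is.na(role) & role == "consumer"])
  if (p_mass + c_mass == 0) stop("no role-assigned bins")
  list(pc = if (c_mass > 0) p_mass / c_mass else Inf,
       producer_fraction = p_mass / (p_mass + c_mass),
       p_mass = p_mass, c_mass = c_mass,
       excluded_mass = sum(assignment$abundance) - p_mass - c_mass,
       infinite = c_mass == 0)
}

#' Fraction of bins assigned a phylogenetic identity
#' @param assignment Data frame from [assign_bins()].
#' @return Fraction in `[0, 1]`.
#' @export
assignment_rate <- function(assignment) {
  if (nrow(assignment) == 0L) stop("no bins")
  mean(assignment$assigned)
}
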