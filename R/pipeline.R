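#' End-to-end analysis parameters
#'
#' Defaults are the study's stated values: MspI digestion of 341F/907R
#' amplicons, 1-bp fragment binning and assignment tolerance, a 3-SD
#' baseline-noise exclusion, a 40% dissimilarity grouping cutoff, and read
#' filters of 300 bp / mean Q25 / homopolymer runs of at most 6. All are
#' overridable and the full parameter set is echoed into every report.
#'
#' @param enzyme_name Restriction enzyme (`"MspI"`, `"HaeIII"`, `"HinfI"`).
#' @param forward,reverse Primer sequences.
#' @param tol_bp Binning/assignment tolerance (bp).
#' @param noise_k Baseline-noise exclusion multiplier (SDs).
#' @param cutoff Dissimilarity grouping cutoff.
#' @param predictors Climate predictors to regress P/C on.
#' @param min_len,min_avg_q,max_hp Read QC thresholds.
#' @param outlier_factor Order-of-magnitude P/C outlier factor.
#' @param nmds_starts,nmds_k NMDS starts and embedding dimension.
#' @param seed Seed for the NMDS random starts.
#' @return Parameter list.
#' @export
pipeline_params <- function(enzyme_name = "MspI",
                            forward = "CCTACGGGAGGCAGCAG",
                            reverse = "CCGTCAATTCMTTTGAGTTT",
                            tol_bp = 1.0, noise_k = 3, cutoff = 0.40,
                            predictors = c("growing_season_d", "map_mm",
                                           "tmin_c", "tmax_c"),
                            min_len = 300, min_avg_q = 25, max_hp = 6,
                            outlier_factor = 10,
                            nmds_starts = 20, nmds_k = 2, seed = 1L) {
  as.list(environment())
}

#' Process one sample's peaks into an assigned community profile
#'
#' Noise filtering, 1-bp binning, relative abundance, taxon assignment and
#' the producer/consumer ratio for a single electropherogram.
#'
#' @param pt A [peak_table()].
#' @param digest_table Digest table from [virtual_digest()].
#' @param params A [pipeline_params()].
#' @return List with `profile`, `assignment`, `pc` and `assignment_rate`.
#' @export
process_sample <- function(pt, digest_table, params = pipeline_params()) {
  filtered <- filter_noise(pt, k = params$noise_k)
  bins <- bin_peaks(filtered, tol_bp = params$tol_bp)
  profile <- relative_abundance(bins, sample_id = pt$sample_id)
  assignment <- assign_bins(profile, digest_table, tol_bp = params$tol_bp)
  list(profile = profile, assignment = assignment,
       pc = producer_consumer_ratio(assignment),
       assignment_rate = assignment_rate(assignment))
}

#' Run the full fingerprint analysis on a study bundle
#'
#' Virtual digest of the reference library, per-sample peak processing and
#' producer/consumer ratios, Bray-Curtis dissimilarity, NMDS ordination and
#' dissimilarity-cutoff grouping, order-of-magnitude P/C outlier removal
#' (locations taken as the Koppen class), and the P/C regression against
#' each configured climate predictor. When reads are present the read QC,
#' demultiplexing and per-sample pass-rate summary are included.
#'
#' @param bundle A study bundle from [simulate_study()] (or an equivalently
#'   shaped list built from files).
#' @param params A [pipeline_params()].
#' @param ordinate Compute the dissimilarity matrix, grouping and NMDS
#'   (default `TRUE`); turn off for regression-only replicate experiments.
#' @return An analysis report list; every block carries the inputs it used.
#' @export
run_all <- function(bundle, params = pipeline_params(), ordinate = TRUE) {
  for (need in c("refs", "metadata", "peak_tables")) {
    if (is.null(bundle[[need]])) stop("bundle is missing '", need, "'")
  }
  primers <- primer_pair(params$forward, params$reverse)
  enz <- enzyme(params$enzyme_name)
  dig <- virtual_digest(bundle$refs, primers, enz)

  samples <- lapply(bundle$peak_tables, process_sample,
                    digest_table = dig$table, params = params)
  profiles <- lapply(samples, `[[`, "profile")
  pc <- vapply(samples, function(s) s$pc$pc, numeric(1))

  D <- NULL; groups <- NULL; ord <- NULL
  if (ordinate) {
    D <- dissimilarity_matrix(profiles, tol_bp = params$tol_bp)
    groups <- cluster_groups(D, cutoff = params$cutoff)
    ord <- nmds(D, k = params$nmds_k, n_starts = params$nmds_starts,
                seed = params$seed)
  }

  finite <- is.finite(pc)
  site_loc <- bundle$metadata$koppen[match(names(pc), bundle$metadata$site_id)]
  kept <- remove_pc_outliers(pc[finite], site_loc[finite],
                             factor = params$outlier_factor)
  regressions <- lapply(params$predictors, function(p) {
    fit_pc_vs_climate(kept$retained, bundle$metadata, predictor = p,
                      excluded = kept$excluded)
  })
  names(regressions) <- params$predictors

  qc <- NULL
  if (!is.null(bundle$reads)) {
    verdicts <- qc_filter_reads(bundle$reads, primer = params$forward,
                                barcode_map = bundle$barcode_map,
                                min_len = params$min_len,
                                min_avg_q = params$min_avg_q,
                                max_hp = params$max_hp)
    passed <- bundle$reads[verdicts$passed, , drop = FALSE]
    dmx <- demultiplex(passed, bundle$barcode_map)
    qc <- list(
      n_reads = nrow(bundle$reads),
      n_passed = nrow(passed),
      pass_rate = mean(verdicts$passed),
      reasons = table(unlist(strsplit(
        verdicts$reasons[!verdicts$passed], ",", fixed = TRUE))),
      reads_per_sample = vapply(dmx$by_sample, nrow, integer(1)),
      n_unmatched = nrow(dmx$unmatched))
  }

  list(
    params = params,
    digest = list(table = dig$table, excluded = dig$excluded),
    pc = data.frame(sample_id = names(pc), pc = unname(pc),
                    assignment_rate = vapply(samples, `[[`, numeric(1),
                                             "assignment_rate"),
                    stringsAsFactors = FALSE),
    outliers = kept$excluded,
    dissimilarity = D,
    groups = groups,
    nmds = ord,
    regressions = regressions,
    qc = qc
  )
}

#' Write an analysis report to disk
#'
#' The report proper goes to versioned JSON; the dissimilarity matrix, NMDS
#' coordinates and per-sample P/C table go to TSV beside it.
#'
#' @param report Report list from [run_all()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  json <- list(
    schema_version = "1.0",
    params = report$params,
    excluded_references = report$digest$excluded,
    excluded_outliers = report$outliers,
    n_groups = length(unique(report$groups)),
    groups = as.list(report$groups),
    stress = report$nmds$stress,
    nmds_converged = report$nmds$converged,
    regressions = lapply(report$regressions, function(r) {
      r[c("predictor", "slope", "intercept", "r", "r_squared",
          "signed_r_squared", "p_value", "n")]
    }),
    qc = if (!is.null(report$qc)) {
      list(n_reads = report$qc$n_reads, n_passed = report$qc$n_passed,
           pass_rate = report$qc$pass_rate,
           reads_per_sample = as.list(report$qc$reads_per_sample),
           n_unmatched = report$qc$n_unmatched)
    }
  )
  jsonlite::write_json(json, fp("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.table(report$pc, fp("pc_values.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(report$nmds$points),
                                report$nmds$points),
                     fp("nmds_coords.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$dissimilarity, fp("dissimilarity.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(report$digest$table, fp("digest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read the shipped nifH OTU count table
#'
#' @param path Path to a nifH count TSV (default: the table shipped with the
#'   package).
#' @return Data frame with column `otu`, one count column per site, and
#'   `order`.
#' @export
read_nifh_table <- function(path = system.file("extdata",
                                               "nifh_otu_counts.tsv",
                                               package = "hypolithr")) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
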