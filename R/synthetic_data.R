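#' Configuration for the synthetic hypolith study generator
#'
#' Defaults emulate the structure of a worldwide hypolith survey: 64 site
#' communities spanning growing seasons of ~0-92 days per year, a reference
#' library whose producer (cyanobacterial/chemoautotrophic) taxa make up a
#' configurable fraction, a log-linear decline of the producer/consumer
#' ratio with growing season, electropherogram size-calling error and
#' below-threshold spurious peaks, and pyrosequencing-style reads with
#' plantable quality defects.
#'
#' The default trophic model `log(P/C) = beta0 + beta1 * g + N(0, sigma_pc)`
#' has `beta0 = log(2.5)` and `beta1 = (log(0.5) - log(2.5)) / 92`, so the
#' noise-free P/C falls from 2.5 at g = 0 to 0.5 at g = 92 days — producer
#' shares of roughly 71% down to 33%.
#'
#' @param seed Integer seed; mandatory — every stochastic draw is
#'   reproducible from (config, seed).
#' @param n_taxa Number of reference taxa (>= 2).
#' @param producer_fraction Fraction of taxa assigned the producer role.
#' @param n_sites Number of site communities.
#' @param g_range Growing-season range in days/yr.
#' @param beta0,beta1,sigma_pc Parameters of the log-linear P/C model.
#' @param trf_min,trf_spacing Smallest planted terminal-fragment size and the
#'   spacing between consecutive taxa's fragments (bp).
#' @param insert_len Length of the random insert between the primer sites.
#' @param size_call_sd Size-calling error SD in bp.
#' @param spurious_peak_rate Poisson mean number of spurious baseline peaks
#'   per electropherogram.
#' @param noise_mean,noise_sd Baseline-noise statistics (signal units).
#' @param area_scale Total fluorescence area of a sample's true peaks.
#' @param area_sdlog Log-normal SD of per-peak area noise.
#' @param n_seq_sites Number of representative sites given simulated reads.
#' @param n_reads Reads per sequenced site.
#' @param read_error_rate Per-base substitution error rate (applied
#'   downstream of the barcode+primer region).
#' @param defect_rate Fraction of reads given one planted QC defect.
#' @param barcode_len Barcode length (nt).
#' @return Validated configuration list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_taxa = 40L,
                       producer_fraction = 0.4,
                       n_sites = 64L,
                       g_range = c(0, 92),
                       beta0 = log(2.5),
                       beta1 = (log(0.5) - log(2.5)) / 92,
                       sigma_pc = 0.4,
                       trf_min = 40L,
                       trf_spacing = 5L,
                       insert_len = 400L,
                       size_call_sd = 0.15,
                       spurious_peak_rate = 5,
                       noise_mean = 50,
                       noise_sd = 10,
                       area_scale = 5e4,
                       area_sdlog = 0.2,
                       n_seq_sites = 4L,
                       n_reads = 2000L,
                       read_error_rate = 0.005,
                       defect_rate = 0.05,
                       barcode_len = 8L) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  rates <- c(cfg$sigma_pc, cfg$size_call_sd, cfg$spurious_peak_rate,
             cfg$noise_sd, cfg$area_sdlog, cfg$read_error_rate,
             cfg$defect_rate)
  if (any(rates < 0)) stop("rates and SDs must be >= 0")
  if (cfg$producer_fraction <= 0 || cfg$producer_fraction >= 1) {
    stop("producer_fraction must lie in (0, 1)")
  }
  if (cfg$n_taxa < 2) stop("need at least 2 taxa")
  structure(cfg, class = "sim_config")
}

# Small genus pools the generator cycles through; diazotroph status follows
# the order rank (Nostocales among producers; Burkholderiales, Rhizobiales,
# Rhodospirillales among consumers).
.producer_pool <- data.frame(
  lineage = c("Cyanobacteria;Cyanophyceae;Oscillatoriales;Phormidiaceae;Phormidium",
              "Cyanobacteria;Cyanophyceae;Chroococcidiopsidales;Chroococcidiopsidaceae;Chroococcidiopsis",
              "Cyanobacteria;Cyanophyceae;Synechococcales;Synechococcaceae;Synechococcus",
              "Cyanobacteria;Cyanophyceae;Nostocales;Nostocaceae;Nostoc"),
  diazotroph = c(FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE)

.consumer_pool <- data.frame(
  lineage = c("Actinobacteria;Actinomycetia;Actinomycetales;Micrococcaceae;Arthrobacter",
              "Bacteroidetes;Cytophagia;Cytophagales;Hymenobacteraceae;Hymenobacter",
              "Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae;Burkholderia",
              "Proteobacteria;Alphaproteobacteria;Rhizobiales;Rhizobiaceae;Rhizobium",
              "Proteobacteria;Alphaproteobacteria;Rhodospirillales;Rhodospirillaceae;Azospirillum",
              "Acidobacteria;Blastocatellia;Blastocatellales;Blastocatellaceae;Blastocatella",
              "Deinococcus-Thermus;Deinococci;Deinococcales;Deinococcaceae;Deinococcus",
              "Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas"),
  diazotroph = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE)

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Rewrite an amplicon so that (a) its first MspI site sits exactly at the
# planted position and (b) no homopolymer run exceeds 6 nt. Only insert
# positions are touched.
.sanitize_amplicon <- function(chars, planted_start, insert_lo, insert_hi) {
  site <- c("C", "C", "G", "G")
  for (pass in 1:100) {
    changed <- FALSE
    n <- length(chars)
    # disrupt any recognition site upstream of the planted one
    for (q in seq_len(planted_start - 1L)) {
      if (q + 3L <= n && all(chars[q:(q + 3L)] == site)) {
        pos <- max(q, insert_lo)         # first site char inside the insert
        chars[pos] <- "A"
        changed <- TRUE
      }
    }
    # break homopolymer runs longer than 6
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    long <- which(r$lengths > 6L)
    for (li in long) {
      run_start <- ends[li] - r$lengths[li] + 1L
      pos <- max(run_start + 3L, insert_lo)
      pos <- min(pos, insert_hi, ends[li])
      if (pos >= planted_start && pos <= planted_start + 3L) {
        pos <- if (planted_start + 4L <= min(insert_hi, ends[li])) {
          planted_start + 4L
        } else {
          max(insert_lo, run_start)
        }
      }
      if (pos < insert_lo || pos > insert_hi) next
      chars[pos] <- if (r$values[li] == "T") "G" else "T"
      changed <- TRUE
    }
    if (!changed) break
  }
  chars
}

#' Generate a synthetic reference library with known terminal fragments
#'
#' Each reference is a random 5' flank, the forward-primer site, a random
#' insert carrying one engineered MspI site, the reverse-complemented
#' reverse-primer site, and a random 3' flank. Planted terminal-fragment
#' sizes start at `trf_min` and step by `trf_spacing`, so they are unique and
#' well separated. Inserts are rewritten so no earlier recognition site or
#' homopolymer run longer than 6 nt appears; every record is verified against
#' the digest functions before being returned.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed; defaults to `config$seed`. Pass `NA` to use the
#'   current RNG state.
#' @return List with `refs` (reference library data frame: `id`, `sequence`,
#'   `lineage`, `role`, `diazotroph`) and `digest_truth` (data frame `id`,
#'   `trf_bp`, `role`).
#' @export
make_reference_library <- function(config, seed = config$seed) {
  if (!is.na(seed)) set.seed(seed)
  primers <- primer_pair()
  fwd <- primers$forward
  rcrev <- revcomp(chartr("M", "A", primers$reverse))  # concrete instance of 907R
  enz <- enzyme("MspI")
  n <- config$n_taxa
  trfs <- config$trf_min + config$trf_spacing * (seq_len(n) - 1L)
  amp_len <- nchar(fwd) + config$insert_len + nchar(rcrev)
  if (max(trfs) + 3L > nchar(fwd) + config$insert_len ||
      min(trfs) <= nchar(fwd)) {
    stop("infeasible terminal-fragment spacing for n_taxa = ", n)
  }
  n_prod <- round(config$producer_fraction * n)
  if (n_prod < 1 || n_prod >= n) stop("producer_fraction leaves an empty role")
  roles <- c(rep("producer", n_prod), rep("consumer", n - n_prod))
  pool_idx <- c(((seq_len(n_prod) - 1L) %% nrow(.producer_pool)) + 1L,
                ((seq_len(n - n_prod) - 1L) %% nrow(.consumer_pool)) + 1L)

  seqs <- character(n); lineages <- character(n); diazo <- logical(n)
  insert_lo <- nchar(fwd) + 1L
  insert_hi <- nchar(fwd) + config$insert_len
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in 1:20) {
      insert <- strsplit(.random_dna(config$insert_len), "")[[1]]
      chars <- c(strsplit(fwd, "")[[1]], insert, strsplit(rcrev, "")[[1]])
      chars[trfs[i]:(trfs[i] + 3L)] <- c("C", "C", "G", "G")
      chars <- .sanitize_amplicon(chars, trfs[i], insert_lo, insert_hi)
      amplicon <- paste(chars, collapse = "")
      full <- paste0(.random_dna(25L), amplicon, .random_dna(25L))
      got <- extract_amplicon(full, primers)
      if (is.na(got) || nchar(got) != amp_len) next
      tf <- terminal_fragment(got, enz)
      if (tf$no_site || tf$trf_bp != trfs[i]) next
      if (max_homopolymer_run(got) > 6L) next
      seqs[i] <- full
      ok <- TRUE
      break
    }
    if (!ok) stop("failed to engineer reference ", i)
    pool <- if (roles[i] == "producer") .producer_pool else .consumer_pool
    lineages[i] <- pool$lineage[pool_idx[i]]
    diazo[i] <- pool$diazotroph[pool_idx[i]]
  }
  ids <- sprintf("t%02d", seq_len(n))
  list(
    refs = data.frame(id = ids, sequence = seqs, lineage = lineages,
                      role = roles, diazotroph = diazo,
                      stringsAsFactors = FALSE),
    digest_truth = data.frame(id = ids, trf_bp = as.integer(trfs),
                              role = roles, stringsAsFactors = FALSE)
  )
}

.rdirichlet1 <- function(n, alpha = 1) {
  g <- stats::rgamma(n, shape = alpha)
  g / sum(g)
}

#' Simulate one site community
#'
#' Draws the target producer/consumer ratio from the log-linear model
#' `log(P/C) = beta0 + beta1 * g + N(0, sigma_pc)`, splits total producer
#' mass `P = PC / (1 + PC)` across the producer taxa by a symmetric
#' Dirichlet(1), and likewise the consumer mass across consumer taxa. Uses
#' the current RNG state; seed upstream.
#'
#' @param g Growing season (days/yr), within the configured range.
#' @param roles Character vector of taxon roles, named by taxon id.
#' @param config A [sim_config()].
#' @return List with `abundances` (named vector summing to 1) and `true_pc`.
#' @export
simulate_site_community <- function(g, roles, config) {
  log_pc <- config$beta0 + config$beta1 * g +
    stats::rnorm(1, 0, config$sigma_pc)
  pc <- exp(log_pc)
  p_mass <- pc / (1 + pc)
  ab <- stats::setNames(numeric(length(roles)), names(roles))
  is_p <- roles == "producer"
  ab[is_p] <- p_mass * .rdirichlet1(sum(is_p))
  ab[!is_p] <- (1 - p_mass) * .rdirichlet1(sum(!is_p))
  list(abundances = ab, true_pc = pc)
}

#' Simulate an electropherogram peak table for one community
#'
#' One peak per present taxon at its true terminal-fragment size plus
#' Normal(0, `size_call_sd`) size-calling error, with area proportional to
#' abundance times log-normal noise and height equal to area. Spurious
#' baseline peaks are appended at Poisson(`spurious_peak_rate`) count with
#' heights uniform on (0, `noise_mean + 3 * noise_sd`), i.e. at or below the
#' 3-SD exclusion threshold. Uses the current RNG state.
#'
#' @param sample_id Sample identifier.
#' @param abundances Named abundance vector (sums to 1).
#' @param digest_truth Data frame `id`, `trf_bp` (true fragment per taxon).
#' @param config A [sim_config()].
#' @return A [peak_table()].
#' @export
simulate_electropherogram <- function(sample_id, abundances, digest_truth,
                                      config) {
  trf <- digest_truth$trf_bp[match(names(abundances), digest_truth$id)]
  present <- abundances > 0
  n <- sum(present)
  area <- abundances[present] * config$area_scale *
    exp(stats::rnorm(n, 0, config$area_sdlog))
  sizes <- trf[present] + stats::rnorm(n, 0, config$size_call_sd)
  pk <- data.frame(size_bp = sizes, height = area, area = area)
  n_sp <- stats::rpois(1, config$spurious_peak_rate)
  if (n_sp > 0) {
    h <- stats::runif(n_sp, 0, config$noise_mean + 3 * config$noise_sd)
    pk <- rbind(pk, data.frame(
      size_bp = stats::runif(n_sp, 30, max(digest_truth$trf_bp) + 50),
      height = h, area = h))
  }
  peak_table(sample_id, pk, config$noise_mean, config$noise_sd)
}

.mutate_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1L)
}

#' Simulate pyrosequencing reads for one community
#'
#' Reads are drawn multinomially across taxa by abundance; each read is the
#' sample barcode followed by a prefix of the taxon's amplicon (so the
#' forward primer sits directly after the barcode), with per-base
#' substitution errors applied downstream of the barcode+primer region and
#' phred qualities around Q38. A configured fraction of reads receives one
#' planted QC defect (too_short, low_quality, ambiguous, homopolymer,
#' no_primer or no_barcode), logged in the ground truth. Uses the current
#' RNG state.
#'
#' @param sample_id Sample identifier.
#' @param abundances Named abundance vector.
#' @param refs Reference library data frame (`id`, `sequence`).
#' @param barcode Barcode prefix for this sample.
#' @param barcode_map Full barcode map (used to keep corrupted barcodes from
#'   colliding with another sample's barcode).
#' @param config A [sim_config()].
#' @return List with `reads` (data frame `id`, `sequence`, `qualities`) and
#'   `truth` (data frame `id`, `sample_id`, `taxon`, `defect`).
#' @export
simulate_reads <- function(sample_id, abundances, refs, barcode, barcode_map,
                           config) {
  primers <- primer_pair()
  amplicons <- vapply(refs$sequence, extract_amplicon, character(1),
                      primers = primers, USE.NAMES = FALSE)
  names(amplicons) <- refs$id
  n <- config$n_reads
  taxa <- sample(names(abundances), n, replace = TRUE, prob = abundances)
  defect <- rep("none", n)
  n_def <- round(config$defect_rate * n)
  if (n_def > 0) {
    kinds <- c("too_short", "low_quality", "ambiguous", "homopolymer",
               "no_primer", "no_barcode")
    defect[sample.int(n, n_def)] <- sample(kinds, n_def, replace = TRUE)
  }
  bc_len <- nchar(barcode)
  p_len <- nchar(primers$forward)
  seqs <- character(n)
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    amp <- amplicons[[taxa[i]]]
    body_len <- round(stats::rnorm(1, 400, 30))
    body_len <- max(320L, min(nchar(amp), body_len))
    body <- substr(amp, 1L, body_len)
    chars <- c(strsplit(barcode, "")[[1]], strsplit(body, "")[[1]])
    err_zone <- (bc_len + p_len + 1L):length(chars)
    hit <- err_zone[stats::runif(length(err_zone)) < config$read_error_rate]
    for (p in hit) chars[p] <- .mutate_base(chars[p])
    q <- pmin(40L, pmax(2L, round(stats::rnorm(length(chars), 38, 4))))
    d <- defect[i]
    if (d == "too_short") {
      keep <- sample(200:298, 1L)
      chars <- chars[seq_len(keep)]; q <- q[seq_len(keep)]
    } else if (d == "low_quality") {
      q <- pmin(40L, pmax(2L, round(stats::rnorm(length(chars), 15, 3))))
    } else if (d == "ambiguous") {
      pos <- sample((bc_len + p_len + 1L):length(chars), 1L)
      chars[pos] <- "N"
    } else if (d == "homopolymer") {
      pos <- sample((bc_len + p_len + 1L):(length(chars) - 1L), 1L)
      chars <- append(chars, rep("A", 8L), after = pos)
      q <- append(q, rep(30L, 8L), after = pos)
    } else if (d == "no_primer") {
      for (p in bc_len + c(2L, 8L, 14L)) chars[p] <- .mutate_base(chars[p])
    } else if (d == "no_barcode") {
      repeat {
        cand <- chars
        cand[1L] <- .mutate_base(cand[1L])
        pre <- paste(cand[seq_len(bc_len)], collapse = "")
        if (!any(vapply(barcode_map, function(b) startsWith(pre, b),
                        logical(1)))) break
      }
      chars <- cand
    }
    seqs[i] <- paste(chars, collapse = "")
    quals[[i]] <- q
  }
  ids <- sprintf("%s_r%05d", sample_id, seq_len(n))
  list(
    reads = data.frame(id = ids, sequence = seqs, qualities = I(quals),
                       stringsAsFactors = FALSE),
    truth = data.frame(id = ids, sample_id = sample_id, taxon = taxa,
                       defect = defect, stringsAsFactors = FALSE)
  )
}

.koppen_for_g <- function(g) {
  ifelse(g <= 5, "EF",
         ifelse(g <= 30, "ET",
                ifelse(g <= 60, "BWk",
                       ifelse(g <= 90, "BWh", "Af"))))
}

#' Simulate a complete multi-site hypolith study
#'
#' Generates the reference library, site metadata with growing seasons
#' spanning the configured range, one community and electropherogram per
#' site, and pyrosequencing reads for a small set of representative sites
#' (the study design sequences a few representatives in depth while
#' fingerprinting every site). All ground truth is returned; when `out_dir`
#' is given, every artifact is also written as plain text together with an
#' md5 manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param with_reads Generate reads for the representative sites (default
#'   `TRUE`; the fingerprint-only bundle is much faster to simulate).
#' @return Bundle list: `config`, `refs`, `digest_truth`, `metadata`,
#'   `peak_tables`, `true_abundances` (taxa x sites matrix), `true_pc`,
#'   `reads`, `read_truth`, `barcode_map`, and `manifest` when written.
#' @export
simulate_study <- function(config, out_dir = NULL, with_reads = TRUE) {
  lib <- make_reference_library(config)
  set.seed(config$seed + 1L)
  n <- config$n_sites
  g <- round(seq(config$g_range[1], config$g_range[2], length.out = n), 1)
  site_ids <- sprintf("site%02d", seq_len(n))
  metadata <- data.frame(
    site_id = site_ids,
    koppen = .koppen_for_g(g),
    map_mm = round(pmax(0, 15 + 7 * g + stats::rnorm(n, 0, 20)), 1),
    tmin_c = round(-30 + 0.25 * g + stats::rnorm(n, 0, 2), 1),
    tmax_c = NA_real_,
    growing_season_d = g,
    stringsAsFactors = FALSE
  )
  metadata$tmax_c <- round(metadata$tmin_c + 25 + abs(stats::rnorm(n, 0, 3)), 1)

  roles <- stats::setNames(lib$refs$role, lib$refs$id)
  true_ab <- matrix(0, nrow = config$n_taxa, ncol = n,
                    dimnames = list(lib$refs$id, site_ids))
  true_pc <- stats::setNames(numeric(n), site_ids)
  peak_tables <- vector("list", n)
  for (i in seq_len(n)) {
    com <- simulate_site_community(g[i], roles, config)
    true_ab[, i] <- com$abundances
    true_pc[i] <- com$true_pc
    peak_tables[[i]] <- simulate_electropherogram(site_ids[i],
                                                  com$abundances,
                                                  lib$digest_truth, config)
  }
  names(peak_tables) <- site_ids

  reads <- NULL; read_truth <- NULL; barcode_map <- NULL
  if (with_reads && config$n_seq_sites > 0) {
    seq_idx <- unique(round(seq(1, n, length.out = config$n_seq_sites)))
    repeat {
      bcs <- vapply(seq_along(seq_idx),
                    function(i) .random_dna(config$barcode_len), character(1))
      if (!anyDuplicated(bcs)) break
    }
    barcode_map <- stats::setNames(bcs, site_ids[seq_idx])
    parts <- lapply(seq_along(seq_idx), function(j) {
      s <- site_ids[seq_idx[j]]
      simulate_reads(s, true_ab[, s], lib$refs, barcode_map[[s]],
                     barcode_map, config)
    })
    reads <- do.call(rbind, lapply(parts, `[[`, "reads"))
    read_truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  }

  bundle <- list(config = config, refs = lib$refs,
                 digest_truth = lib$digest_truth, metadata = metadata,
                 peak_tables = peak_tables, true_abundances = true_ab,
                 true_pc = true_pc, reads = reads, read_truth = read_truth,
                 barcode_map = barcode_map)
  if (!is.null(out_dir)) bundle$manifest <- write_bundle(bundle, out_dir)
  bundle
}

#' Write a simulated study bundle to a directory
#'
#' Emits the reference FASTA, taxonomy TSV, site metadata TSV, combined peak
#' CSV, noise TSV, FASTQ reads, barcode TSV and ground-truth TSVs, plus an
#' md5 manifest.
#'
#' @param bundle A bundle from [simulate_study()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest data frame (`file`, `md5`), invisibly written as
#'   `manifest.tsv`.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  write_fasta(bundle$refs, fp("references.fasta"))
  write_taxonomy(bundle$refs[, c("id", "lineage", "role", "diazotroph")],
                 fp("taxonomy.tsv"))
  utils::write.table(bundle$metadata, fp("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  peaks <- do.call(rbind, lapply(bundle$peak_tables, function(pt) {
    cbind(sample_id = pt$sample_id, pt$peaks)
  }))
  utils::write.csv(peaks, fp("peaks.csv"), row.names = FALSE, quote = FALSE)
  noise <- data.frame(
    sample_id = names(bundle$peak_tables),
    noise_mean = vapply(bundle$peak_tables, `[[`, numeric(1), "noise_mean"),
    noise_sd = vapply(bundle$peak_tables, `[[`, numeric(1), "noise_sd"))
  utils::write.table(noise, fp("noise.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$digest_truth, fp("digest_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ta <- data.frame(taxon = rownames(bundle$true_abundances),
                   bundle$true_abundances, check.names = FALSE)
  utils::write.table(ta, fp("true_abundances.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(site_id = names(bundle$true_pc),
                                true_pc = bundle$true_pc),
                     fp("true_pc.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bundle$reads)) {
    write_fastq(bundle$reads, fp("reads.fastq"))
    utils::write.table(data.frame(sample_id = names(bundle$barcode_map),
                                  barcode = unname(bundle$barcode_map)),
                       fp("barcodes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(bundle$read_truth, fp("read_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  files <- setdiff(list.files(out_dir), "manifest.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.table(manifest, fp("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest
}
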