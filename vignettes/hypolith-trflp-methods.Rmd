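---
title: "Methods: t-RFLP fingerprinting and trophic-structure analysis of hypolithic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: t-RFLP fingerprinting and trophic-structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypolithr)
```

## The problem

Hypoliths are microbial biofilms on the soil-facing surfaces of translucent
desert stones, typically dominated by cyanobacteria. Comparing such
communities across deserts worldwide raises two linked questions: how do
whole-community fingerprints group across macroclimates, and does the
balance between primary producers (Cyanobacteria and chemoautotrophs) and
heterotrophic consumers track a climate axis such as the growing season —
the number of days per year when temperature, moisture and light jointly
permit photosynthesis?

`hypolithr` implements the full fingerprint-to-statistics pipeline for this
design: terminal restriction fragment length polymorphism (t-RFLP)
processing with taxon assignment by in-silico digestion, the
producer/consumer (P/C) ratio and its regression on climate predictors,
Bray–Curtis/NMDS community ordination with dissimilarity-cutoff grouping,
and the read-level quality control, rarefaction and tallying steps used for
the accompanying amplicon sequencing. A synthetic-data generator provides
ground truth at every stage, so the pipeline's statistical behaviour is
testable end to end.

## In-silico digestion and taxon assignment

Amplicons are delimited by the 341F/907R 16S rRNA primer pair
(`CCTACGGGAGGCAGCAG` / `CCGTCAATTCMTTTGAGTTT`; the degenerate M matches A or
C by IUPAC expansion) and digested in silico, by default with MspI (C^CGG).
The predicted terminal restriction fragment (TRF) runs from the 5'
fluorescently labeled forward-primer end to the first cut; its length is the
between-base cut coordinate, primer included, matching how labeled fragments
migrate on capillary electrophoresis. Conventions worth making explicit:

* **Primer inclusion.** The TRF is measured from the first base of the
  forward-primer annealing site. This is a declared convention — labelled
  fragments physically include the primer — not something the fingerprinting
  literature fixes uniformly.
* **No-site amplicons** keep their full length and are flagged `no_site`:
  an uncut labeled fragment is a real observable, not a missing value.
* **Leftmost matches.** Only the 5'-most forward-primer match is used
  (deterministic, and the 5'-most priming site dominates PCR); the amplicon
  ends at the first reverse site downstream (the shortest product).
* **Mismatches.** Primer matching tolerates 0 mismatches by default
  (configurable); references may contain N but no other ambiguity code, and
  N never satisfies a recognition site.

Observed fragment bins are assigned to the nearest predicted TRF within 1 bp.
Ties — equal distance, or several taxa at one predicted size — are flagged
ambiguous; a trophic role is still assigned when all tied taxa share it.

## Electropherogram processing

* **Noise exclusion.** Peaks at or below `noise_mean + 3 * noise_sd` (peak
  *height* against the per-sample baseline statistics) are excluded; the
  boundary itself is excluded, and the multiplier `k = 3` is configurable.
  Noise statistics are taken per sample from the peak-table sidecar.
* **Binning.** Peaks within 1 bp of one another represent the same taxon.
  We implement this as greedy single-linkage over ascending sizes: adjacent
  peaks with gap ≤ 1 bp join a bin, so a chain of near peaks may span more
  than 1 bp in total. The bin representative is the area-weighted mean size.
* **Abundance.** Relative abundance is the ratio of binned peak *area* to
  the total area of all retained peaks (height gates noise, area measures
  abundance).
* **P/C.** P and C are the summed relative abundances over producer- and
  consumer-assigned bins; unassigned or role-ambiguous mass is excluded and
  reported. C = 0 yields an explicit infinite flag rather than a number.

## Community statistics

Bray–Curtis dissimilarity (`1 - 2*sum(min)/(sum a + sum b)`) is computed
after aligning per-sample bins across samples with the same 1-bp
single-linkage rule (cross-sample alignment is not fixed by the original
binning description; re-using the within-sample rule is the least surprising
choice). Groups are read from a group-average (UPGMA) tree cut at 40%
dissimilarity — the PRIMER-style convention behind "groups at a 40%
dissimilarity cutoff".

NMDS minimises Kruskal stress-1,
$\sqrt{\sum_{i<j}(d_{ij}-\hat d_{ij})^2 / \sum_{i<j} d_{ij}^2}$,
with disparities $\hat d$ fit by pool-adjacent-violators monotone regression
on the dissimilarity ranks (primary tie handling). Coordinates update by a
Guttman transform with step halving, so the accepted stress sequence is
non-increasing by construction. The first start is the classical metric MDS
configuration and the remainder are random; the best of `n_starts = 20`
is returned, reproducible from the seed. An all-equal dissimilarity matrix
is detected up front and returned with a warning and `converged = FALSE`.

The P/C–climate relationship is ordinary least squares of *untransformed*
P/C on one predictor (growing season, mean annual precipitation, minimum or
maximum temperature); a log-P/C option exists but is off by default. The
slope's two-sided p-value uses the t distribution on n − 2 df. Because
signed "R²" values appear in this literature (a coefficient of
determination cannot be negative; the sign evidently encodes the direction
of r), the result reports `r`, `r_squared` and `signed_r_squared =
sign(r)·r²` side by side and asserts no convention. Before fitting, samples
whose P/C exceeds both their location mean and the overall mean by an order
of magnitude (≥10×, leave-one-out means) are excluded and reported.

## Read quality control and rarefaction

A read is removed if it meets *any* criterion: untrimmed length < 300 bp;
arithmetic-mean phred quality < 25; any ambiguous (non-ACGT) base outside
the barcode; a homopolymer run longer than 6 nt ("more than 6 homopolymers"
read as run length, the MOTHUR-style convention — a count-of-runs reading
has no biological rationale); missing primer (0 mismatches by default); or
missing barcode (exact 5' prefix, no error correction). All reasons are
evaluated, so a verdict lists every criterion met. Whether the length filter
applies before or after trimming is not fixed by the stated rules; we use
the untrimmed length.

Rarefaction is analytic:
$E[S(d)] = \sum_i \left(1 - \binom{N-N_i}{d}\big/\binom{N}{d}\right)$,
computed via `lchoose` for stability, with coverage $E[S(d)]/S$. OTU count
vectors are inputs; 97%-similarity OTU construction itself is a named
third-party step and out of scope. Diazotroph screening sums abundance over
lineages matching an editable pattern list seeded with Burkholderiales,
Rhizobiales, Rhodospirillales and Nostocales — curated, not canonical.

## The synthetic study generator

`sim_config()` fixes the study conditions; the generator is the ground truth
for every pipeline stage, not a tuning dial.

* **Scale.** 64 site communities (the scale of a worldwide hypolith
  survey) over growing seasons 0–92 d/yr; 40 reference taxa, 40% producers.
* **Trophic model.** `log(P/C) = β0 + β1·g + ε`, `ε ~ N(0, 0.4)`, with
  `β0 = log 2.5` and `β1 = (log 0.5 − log 2.5)/92`: noise-free P/C falls
  from 2.5 to 0.5 across the range, i.e. producer shares of ~71% down to
  ~33%, matching the spread such surveys report. The generator is
  deliberately log-linear while the fitted model is linear in P/C, so
  recovery tests check the sign and monotonicity of the relationship, not a
  shared functional form. Producer and consumer mass is split within role by
  symmetric Dirichlet(1).
* **References.** Each reference is flank + 341F site + 400-nt random
  insert + reverse-complemented 907R site + flank, with one engineered MspI
  site so planted TRFs start at 40 bp and step by 5 bp (unique, ≥3 bp
  apart). Inserts are rewritten to remove earlier recognition sites and
  homopolymer runs > 6, and every record is verified against the package's
  own digest before release.
* **Electropherograms.** Peak sizes get N(0, 0.15 bp) size-calling error;
  areas are abundance × total-signal 5·10⁴ × log-normal(σ = 0.2) noise,
  height = area. Spurious peaks (Poisson mean 5/sample) draw heights
  uniform on (0, mean + 3·SD] of the baseline noise (mean 50, SD 10), so
  the 3-SD filter removes all of them by construction.
* **Reads.** 2,000 reads for each of 4 representative sites (deep
  sequencing of representatives, fingerprinting of everything — the
  two-step design), drawn multinomially by abundance; per-base substitution
  errors (0.005) apply downstream of the barcode+primer region, so an
  error-free read always retains its identifiers; 5% of reads carry one
  planted, logged QC defect. Sequencing errors can occasionally create
  *genuine* QC failures (e.g. merging two runs into a > 6 homopolymer);
  this is realism, and exact planted-defect recovery is asserted in the
  zero-error limit.

What the generator does **not** emulate: phylogenetically realistic sequence
evolution, 454 flowgram error structure (homopolymer-length miscalls),
partial digestion, pseudo-TRFs, or within-site replicate stone structure.
Passing recovery tests therefore demonstrates the pipeline's statistical
correctness under its own assumptions, not field-data performance.

## Numerical choices and degenerate inputs

* Noise boundary strict (`>`), binning boundary inclusive (`≤ 1 bp`), QC
  boundaries as stated (fail `< 300`, `< 25`, `> 6`).
* Zero total peak area, empty amplicons, all-zero abundance pairs, empty
  diazotroph lists and depth > N are errors, not silent zeros.
* `lchoose` avoids overflow in rarefaction at depths in the thousands.
* NMDS accepts an update only if stress does not increase (step halving to
  1/64 before giving up), guaranteeing the monotone stress contract at the
  cost of occasionally stopping in a local minimum — mitigated by multiple
  starts.
* Problem sizes in the tests (64-site studies, 100 replicate studies,
  10,000-fold resampling on 20 vectors, 1,000 oracle sequences per enzyme)
  were chosen as the smallest scales at which the statistical properties
  under test are clearly resolved.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
bundle <- simulate_study(cfg, with_reads = FALSE)
report <- run_all(bundle, pipeline_params(seed = 42))
report$regressions$growing_season_d[c("slope", "r", "p_value")]
report$nmds$stress
```

The numbered drivers under `analysis/` run the same computation as a
narrative: `01_simulate_study.R` writes the synthetic bundle,
`02_virtual_digest.R` predicts TRFs, `03_trflp_profiles.R` builds assigned
profiles and P/C values, `04_community_ordination.R` ordinates and fits the
climate regressions, and `05_amplicon_qc.R` runs the read-level analyses.

## Known limitations

* Cross-sample bin alignment can, like any single-linkage rule, chain
  drifting fragment sizes across samples into one bin.
* The P/C regression treats each community as one observation; replicate
  stones per location are not modelled.
* The assignment-rate statistic is reported over fragment bins; whether
  published percentages of this kind count raw peaks or binned taxa is
  ambiguous, and the two differ when bins merge peaks.
* Barcode demultiplexing is exact-prefix only; error-correcting barcodes
  are not supported.
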