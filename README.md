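# hypolithr

Terminal restriction fragment length polymorphism (t-RFLP) fingerprinting
and trophic-structure analysis of hypolithic microbial communities.

Hypoliths — cyanobacteria-dominated biofilms under translucent desert
stones — can be fingerprinted across many sites by t-RFLP of the 16S rRNA
gene and compared along macroclimate gradients. This package implements that
analysis end to end:

* **In-silico digestion**: predicted terminal restriction fragment (TRF)
  sizes for a reference library from the 341F/907R amplicon and a
  restriction enzyme (MspI by default; HaeIII, HinfI built in), with full
  IUPAC-degenerate primer matching.
* **Electropherogram processing**: exclusion of peaks within 3 SD of the
  baseline noise, 1-bp single-linkage fragment binning, relative abundance
  as peak-area ratios, nearest-TRF taxon assignment.
* **Trophic statistics**: the producer/consumer ratio
  `P/C = Σ abundance(producers) / Σ abundance(consumers)`, an
  order-of-magnitude outlier rule, and ordinary least squares of P/C on
  growing season (days/yr), precipitation or temperature extremes, with
  `r`, `r²` and signed `r²` reported side by side.
* **Ordination**: Bray–Curtis dissimilarity
  `d = 1 − 2·Σmin(aᵢ,bᵢ)/(Σa+Σb)`, non-metric multidimensional scaling
  minimising Kruskal stress-1 with isotonic (pool-adjacent-violators)
  regression, and community groups from a UPGMA tree cut at 40%
  dissimilarity.
* **Amplicon QC**: the de-noising read filter (length < 300 bp, mean
  quality < 25, ambiguous bases, homopolymer runs > 6, missing
  primer/barcode), barcode demultiplexing, analytic hypergeometric
  rarefaction `E[S(d)] = Σᵢ(1 − C(N−Nᵢ,d)/C(N,d))`, OTU-sharing (Venn)
  tallies, diazotroph screening and nifH count tallies.
* **A synthetic-data generator** that produces reference libraries, site
  communities with a log-linear P/C–growing-season decline, noisy
  electropherograms and defect-planted reads — ground truth for every
  stage.

See `vignettes/hypolith-trflp-methods.Rmd` for the model, conventions and
design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study as a narrative.

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_virtual_digest.R
Rscript analysis/03_trflp_profiles.R
Rscript analysis/04_community_ordination.R
Rscript analysis/05_amplicon_qc.R
```

Output of the ordination step on the default synthetic bundle:

```
Bray-Curtis NMDS stress: 0.292 over 64 communities
Groups at a 40% dissimilarity cutoff: 48
P/C outliers excluded (order-of-magnitude rule): none
P/C ~ growing_season_d  slope -0.0219  r -0.697  signed r^2 -0.487  p 1.51e-10 (n=64)
P/C ~ map_mm            slope -0.0030  r -0.694  signed r^2 -0.481  p 2.12e-10 (n=64)
P/C ~ tmin_c            slope -0.0816  r -0.678  signed r^2 -0.459  p 7.84e-10 (n=64)
P/C ~ tmax_c            slope -0.0761  r -0.649  signed r^2 -0.421  p 6.73e-09 (n=64)
```

The fitted growing-season slope is negative and strongly significant: sites
with shorter growing seasons carry relatively more producers, exactly the
structure the generator planted (`log(P/C)` falling from `log 2.5` at 0 days
to `log 0.5` at 92 days, plus noise). The preceding profile step reports a
100% taxon-assignment rate and recovers the true P/C within 20% for 98% of
sites; the generator's spurious baseline peaks are entirely removed by the
3-SD noise filter.

Equivalently, in R:

```r
library(hypolithr)
bundle <- simulate_study(sim_config(seed = 42), with_reads = FALSE)
report <- run_all(bundle, pipeline_params(seed = 42))
report$regressions$growing_season_d$slope   # negative
report$nmds$stress
```

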