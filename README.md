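# taxadiel

Diel rhythmicity and pathway timing in taxon-binned metatranscriptomes.

Surface-ocean microbial eukaryotes (protists) synchronise much of their
transcription to the 24-h light/dark cycle. Community metatranscriptomes
sampled repeatedly over several days make that synchrony measurable — but
only after the reads are partitioned into per-taxon "environmental bins",
normalised within each bin, screened for periodicity with multiplicity
control, and summarised at the pathway level. `taxadiel` implements that
analysis as a tested, reusable pipeline for anyone working with
time-resolved community transcriptomics. It consumes the tabular outputs
of an assembly/annotation workflow (contig counts, taxonomic and
gene-family annotations, a taxonomy, pathway membership, a reference
presence matrix) and provides:

* **Environmental taxon bins and bin-denominated FPKM.** Contigs assigned
  to a taxonomic node or any of its daughters form one bin. Abundance is
  FPKM with the *bin* as denominator:
  `FPKM(c, s) = (n_cs / (L_c/1000)) / (M_bin(c),s / 10^6)`, where `n_cs`
  is the fragment count of contig `c` in sample `s`, `L_c` its length and
  `M_bin,s` the total fragments mapped to the contig's bin in that sample.
  Contig values are summed per (bin, gene family) and can be rolled up
  the taxonomy (species → genus → order ...).
* **Completeness scoring.** A core gene-family set is derived from a
  reference presence matrix (families present in ≥ 95% of reference
  proteomes); bins are scored by the percentage of core families they
  express and filtered on a strict detected-family cutoff.
* **Nonparametric diel rhythmicity detection.** Each (bin, family) FPKM
  series, grouped by time of day, is screened with an umbrella rank test:
  for every cyclic (peak, trough) placement, a Jonckheere–Terpstra-type
  statistic counts order-concordant observation pairs along the rising
  and falling arms (ties ½). Per-pattern permutation p-values (exhaustive
  or Monte-Carlo with the add-one estimator) are Bonferroni-combined over
  the `G(G−1)` patterns, and one Benjamini–Hochberg correction is applied
  across all series (FDR < 0.05). Significant families receive a peak
  hour on the sampling grid.
* **Pathway×time enrichment.** For every (bin, hour, pathway), a 2×2
  table of *in pathway* × *diel-peaking-at-that-hour* over the bin's
  tested families, tested one-sided with Fisher's exact test and
  BH-corrected across the run.
* **Ordination.** Replicate-averaged (bin × time point) observation
  matrices, prevalence-filtered (strict >5%) and row-normalised to sum 1;
  Bray–Curtis dissimilarities; global and per-bin NMDS (Kruskal stress-1
  via vegan); per-hour profile summaries (mean, SE over the
  `days × replicates` observations, min–max normalised traces).
* **A synthetic diel metatranscriptome generator.** Every input table the
  pipeline consumes, generated from explicit parameters and a seed, with
  a ground-truth ledger (which families are diel and at what phase, which
  pathway×hour pairs are enriched, which families are core). Diel
  families follow `E[n] = μ(1 + a·cos(2π(t − φ)/24))` on
  negative-binomial noise (`Var = μ + θμ²`). The defaults emulate a
  4-day, 4-hourly, duplicate-sample cruise design: 48 samples, 8
  observations per time-of-day group.

## Worked example

A fully synthetic run — six genus bins, 300 gene families each, 15% truly
diel, one pathway enrichment planted at 06:00 in `genus01`:

```r
library(taxadiel)

cfg <- default_config()
cfg$pathways$planted <- data.frame(taxon_id = "genus01",
                                   pathway_id = 2, hour = 6)
res <- run_pipeline(cfg, "demo")
#> simulate: 3780 contigs x 48 samples, 6 genera
#> quantify: 1800 (bin, family) rows across 6 bins
#> completeness: 6/6 bins pass the >150-family filter
#> rhythm: 291/1800 families called diel (FDR 0.05)
#> enrichment: 1/432 retained tables enriched
#> ordination: 144 observation rows
```

The rhythm table carries one row per (bin, family) with the umbrella
statistic, raw and BH-adjusted p-values and the assigned peak hour:

```r
res$rhythm[res$rhythm$is_diel][1:3]
#>    taxon_id gene_family_id     p_raw p_adjusted peak_hour
#> 1:  genus01         K00005 0.0029997 0.01874813         6
#> 2:  genus01         K00007 0.0029997 0.01874813         6
#> 3:  genus01         K00014 0.0029997 0.01874813         6
```

The 291 diel calls cover the ~285 truly rhythmic families (270 background
plus the pathway-planted ones) with a handful of extras consistent with
the 5% FDR, and the single enrichment the run reports is exactly the
planted (genus01, 06:00, pathway 2) triple:

```r
res$enrichment$results[res$enrichment$results$enriched == TRUE]
#>    taxon_id  hour pathway_id  a b c   d odds_ratio   p_adjusted
#> 1:  genus01     6       pw02 17 4 9 270      127.5 3.123881e-15
```

`a = 17` of the pathway's 21 detected member families peak at 06:00,
against 9 of the 279 non-members — the one-sided Fisher test puts the
over-representation at `p_adj ≈ 3e-15`. Per-family profiles summarise the
n = 8 observations behind each sampling hour:

```r
profile_summary(res$abundance, res$design, "genus01", "K00005")
#>     hour     n      mean        se    minmax
#> 1:     2     8 2504.5259 338.71506 1.0000000
#> 2:     6     8 2397.2609 478.79446 0.9571715
#> ...
```

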