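---
title: "Detecting diel transcriptional rhythms in taxon-binned metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting diel transcriptional rhythms in taxon-binned metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxadiel)
```

## The analysis problem

Open-ocean protist communities are sampled here on a diel grid: six times
of day four hours apart (06:00, 10:00, 14:00, 18:00, 22:00, 02:00), over
four consecutive days, with duplicate samples — 48 samples in all, and
`4 days × 2 replicates = 8` observations behind every time-of-day group.
Reads are assembled and annotated upstream; `taxadiel` starts from the
resulting tables (contig counts and lengths, contig → taxon and
contig → gene-family annotations, a taxonomy, pathway membership, a
reference presence matrix) and asks, per organism proxy: *which gene
families cycle over 24 h, when do they peak, and which pathways
concentrate their activity at particular hours?*

## Environmental taxon bins and bin-denominated FPKM

A bin at a target rank (genus by default) is the set of contigs assigned
to that node *or any of its descendants*. Quantification is FPKM with the
bin, not the library, as denominator:

$$\mathrm{FPKM}_{c,s} = \frac{n_{c,s} / (L_c/10^3)}{M_{b(c),s}/10^6},$$

with $n_{c,s}$ the fragment count, $L_c$ the contig length and
$M_{b,s}$ the total fragments mapped to bin $b$ in sample $s$. Dividing
by the bin total removes between-sample differences in how much of the
library each taxon captured, so within-bin temporal profiles are
comparable across samples. Two consequences worth knowing:

* multiplying all counts of a (bin, sample) by a constant leaves every
  FPKM in that (bin, sample) unchanged (numerator and denominator scale
  together), and member fragments always sum to $M_{b,s}$;
* contigs with a taxon but no gene-family annotation still count toward
  $M$ (the denominator is "reads mapped to the bin") but are reported
  only as an unannotated total, not in the family tensor.

A (bin, sample) with $M = 0$ yields FPKM 0 and a flag, never NaN.
Family-level values are sums over the bin's contigs sharing an
annotation, and `rollup()` integrates bins up the taxonomy by summing
descendant values into ancestors.

## Completeness screening

Deep bins are separated from fragmentary ones before rhythm testing. A
core gene-family set is derived from a reference presence matrix —
families present in at least 95% of reference proteomes (inclusive
threshold; the cutoff is a parameter since "approximately 95%" admits
several realisations). Each bin reports its detected-family count and the
percentage of core families it expresses; the inclusion filter is a
strict `> min_families` on detected families (901 passes a cutoff of
900; 900 does not), with 900 the convention for deeply sequenced marine
communities. Detection means positive abundance in at least one sample,
assessed after any roll-up, consistent with the bin definition.

## The umbrella rank test

Rhythm detection must tolerate non-sinusoidal waveforms, overdispersed
counts and small per-group samples, so it is built entirely on ranks.
For $G$ time-of-day groups on the cyclic 24-h axis, every ordered pair
(peak $p$, trough $q$), $p \ne q$, defines an *umbrella pattern*: a
rising arm walking the clock from $q$ to $p$ and a falling arm from $p$
back to $q$ (the trough is left out of the falling arm so each group
pair is compared exactly once — the Mack–Wolfe convention). There are
$G(G-1) = 30$ patterns for the six sampling hours. The pattern statistic
is the Jonckheere–Terpstra-type concordance count

$$S = \sum_{(a \prec b)\,\text{rising}} \#\{x \in a,\, y \in b : x < y\}
    + \tfrac12\#\{x = y\}
    \;+\; \sum_{(a \prec b)\,\text{falling}} \#\{x > y\} + \tfrac12\#\{x = y\},$$

whose maximum is the number of compared pairs. $S$ depends on the data
only through ranks, so any strictly monotone transform of a series
(scaling, shifting, logs) leaves the test invariant.

Per-pattern p-values come from the permutation null — all reassignments
of the pooled observations to groups with sizes fixed. The exhaustive
engine enumerates the $n!$ orderings when $n! \le 10^6$; otherwise
`n_perm` Monte-Carlo permutations are drawn and $p = (r+1)/(n_\mathrm{perm}+1)$
(the add-one estimator, never zero). One set of permutation draws is
shared across the 30 patterns of a series. The series-level p-value is
the Bonferroni combination $p_\mathrm{raw} = \min(1,\; 30\,\min_j p_j)$
— conservative, which the false-positive-rate tests confirm. A series
with zero variance is assigned $p = 1$ outright.

**Batch engine.** Screening $10^4$–$10^5$ series would be slow with a
fresh null per series, so `detect_rhythms()` draws one set of `n_perm`
permutations of a tie-free rank vector and reuses that null distribution
for every series. For tie-free data this is exact — the statistic is
distribution-free given the group sizes. Series with ties (zero counts
produce them) have a tie-adjusted statistic that is stochastically
*narrower* than the tie-free null, so their p-values are conservative;
FDR control is preserved, at a small cost in power on sparse series. The
`per_series` engine, and `rain_test()` on a single series, permute the
series' own values instead.

**Multiplicity.** One Benjamini–Hochberg step-up correction is applied
across *all* (bin, family) series pooled — the discovery set is a single
test family, so per-bin differences in family counts do not distort the
FDR — with `fdr_scope = "per_bin"` available for comparison. A family is
diel when its adjusted p falls below the 0.05 FDR level; the reported
critical value is $(k/m)\,\alpha$ for $k$ discoveries among $m$ tests.

**Peak assignment.** The peak hour is the sampling hour of the
minimal-p pattern's peak group. The Monte-Carlo null cannot resolve
p-values below $1/(n_\mathrm{perm}+1)$, so strongly rhythmic series
leave many patterns tied at that floor and the argmin is censored. Ties
are resolved by a phase estimate: the tied pattern whose peak hour lies
nearest (cyclically) to the first-harmonic — cosinor — phase of the six
hourly means,

$$\hat\varphi = \frac{24}{2\pi}\,\operatorname{atan2}\!\Big(\textstyle\sum_g \bar{x}_g \sin \theta_g,\; \sum_g \bar{x}_g \cos \theta_g\Big),$$

then by the largest peak-group mean, then by pattern order. The cosinor
is the natural phase estimator for the sinusoidal alternative the test
screens, and in recovery simulations at amplitude 1.0 it assigns
essentially all detected planted families their true hour, where the
plain largest-group-mean rule (kept as `peak_rule = "pattern_mean"`)
misassigns roughly one in six to an adjacent hour.

## Pathway×time enrichment

For each bin, hour $t$ and pathway, the bin's tested families are cross-
classified as *in/out of the pathway* × *diel with peak at $t$ / not*;
tables whose pathway has no detected member in the bin are removed
before testing. The one-sided Fisher exact p is the upper hypergeometric
tail (depletion is not of interest; a two-sided option exists), the odds
ratio is the unconditional cross-product $ad/bc$, and one BH correction
spans all retained tables of a run. The family universe is the bin's
*tested* families, not a global catalogue, so absent families never
inflate the $d$ cell. "Diel at $t$" means peak assigned to $t$; the
alternative reading (diel at any hour) is available as
`mode = "any_time"`.

## Ordination and profiles

The observation matrix has one row per (bin, day×hour time point) — 48
bins × 24 time points = 1,152 rows in the full design — holding
replicate-averaged family FPKM. Averaging precedes the prevalence filter
(columns must be positive in strictly more than 5% of rows), which
precedes row normalisation to sum 1; the steps do not commute, and the
order is fixed and regression-tested. All-zero rows are kept (flagged)
so the row bookkeeping is stable. Bray–Curtis dissimilarity
$d(u,v) = 1 - 2\sum_j \min(u_j,v_j) / (\sum_j u_j + \sum_j v_j)$
feeds NMDS (vegan's `metaMDS`, Kruskal stress-1, `trymax` random
restarts, seeded and centered; non-convergence is reported, not thrown).
Exact stress values and coordinates are data- and
implementation-dependent, so tests assert stress levels and topology
(e.g. embeddable configurations recover stress ≈ 0; diel-dominated bins
show clock-like orderings where hour-adjacent time points are closer
than hour-opposite ones) rather than fixed coordinates. Per-family
profiles report, per sampling hour, the mean and standard error of the
$n = $ days × replicates pooled observations and a min–max-normalised
trace of the hourly means (a constant trace maps to 0.5 and is flagged).

## The synthetic community generator

All validation runs on generated data with known truth. The generator
emulates the tables an assembly/annotation workflow produces:

* **Design**: 6 times × 4 days × 2 replicates by default.
* **Counts**: a truly diel family with peak $\varphi$ and relative
  amplitude $a$ has expectation
  $\mu_t = \mu_0\,(1 + a\cos(2\pi(t-\varphi)/24))$; non-diel families
  are flat. Counts are negative-binomial,
  $\mathrm{Var} = \mu + \theta\mu^2$, drawn independently per contig and
  sample, with each family's expectation split equally across its
  contigs. Defaults: $\mu_0 = 50$, $\theta = 0.3$ (typical RNA-seq
  overdispersion), amplitude 1.0, two contigs per family, lengths
  uniform on 300–3,000 bp (assembly minimum 300 bp). Amplitudes that
  would push the expectation negative at a sampled hour are rejected.
* **Taxonomy**: genera are nested under order/class/lineage nodes, and
  contigs are annotated at the genus node or at one of two species
  children, so bin construction must exercise the daughter-node rule.
* **Pathways**: drawn from the family universe with configurable sizes;
  a planted (taxon, pathway, hour) enrichment draws the pathway's
  members from that taxon and sets exactly `round(rate × size)` of them
  diel at the planted hour (rate 0.8 by default) — deterministic
  planting keeps the expected contingency counts exact.
* **Reference presence**: core families present in ≥ 95% of reference
  taxa by construction, others at a configurable background prevalence.
* **Truth ledger**: per (taxon, family) diel flag, phase and amplitude;
  planted enrichments; core flags. Identical (seed, parameters)
  reproduce byte-identical outputs.

What the generator does *not* emulate — and what passing tests therefore
do not certify about field data: annotation error and chimeric contigs,
day-to-day autocorrelation or replicate random effects (replicates are
independent draws; the real day-to-day variance structure of ocean
transcript abundances is unknown), compositional coupling between
families, internal spike-in standards, and asymmetric waveforms beyond
the umbrella family. The rank test itself does not assume the cosine
form — only a single rise and fall per cycle.

## Numerical and design choices

* Hours live on a `[0, 24)` clock; 02:00 sorts before 06:00. Designs
  need at least two evenly spaced times; the rhythm test needs at least
  three groups.
* Ties in the statistic count ½ per pair (mid-rank convention).
* Exhaustive permutation is auto-selected up to $10^6$ orderings;
  Monte-Carlo otherwise, `n_perm = 10,000` by default with the seed
  recorded in the output. At `n_perm` permutations the smallest
  attainable series-level p is $30/(n_\mathrm{perm}+1)$; detecting a
  fraction $f$ of diel families under global BH at level $\alpha$
  requires that floor to be below $f\alpha$, which is worth checking
  before scaling `n_perm` down.
* BH discoveries use a strict `adjusted < alpha`; the inclusion filter
  a strict `>`; the prevalence filter a strict `>`; the core threshold
  an inclusive `≥`.
* `enrich_all` reports the enumerated / retained / enriched counts so
  the filtering bookkeeping of a run is auditable.
* All randomness in `run_pipeline` flows from one master seed via fixed
  per-stage sub-streams, so stages are individually reproducible.
* Simulation-based tests are sized to run on a laptop: the FDR suite
  uses 20 seeds × 8,000 series at `n_perm = 2,000`; recovery suites use
  `n_perm = 10,000` where the Monte-Carlo floor permits discovery at
  the simulated diel fractions.

## Known limitations

* The umbrella test's Bonferroni combination over 30 patterns is
  conservative; a max-statistic permutation combination would be
  tighter but is deliberately not the default, to keep per-pattern
  p-values interpretable and the combination auditable.
* Phase resolution equals the sampling grid (4 h); no finer phase is
  estimated or reported.
* Bray–Curtis does not satisfy the triangle inequality; NMDS is used
  precisely because it only needs rank-order dissimilarities.
* Order-level analyses reuse the genus-level machinery on rolled-up
  bins; contigs annotated *above* the roll-up's source rank are not
  recovered by `rollup()` (bins are re-built at the coarser rank when
  that matters).
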