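---
title: "poolsex: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{poolsex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsex)
```

poolsex locates sex-determining regions from male/female pooled
whole-genome sequencing and quantifies how sex chromosomes are recruited
and replaced across a clade. This vignette explains the statistical model
behind each stage, the tunable parameters and their defaults, the design
choices that were genuinely open, and what the synthetic-data generator
does and does not emulate.

## The pool-seq signal model

In a pooled design, equimolar DNA from N males and N' females is
sequenced as two pools, and allele frequencies are estimated from read
counts rather than genotypes. A sex-limited haplotype (Y in an XY system,
W in ZW) is carried by half the chromosomes of the heterogametic sex and
none of the other sex. A SNP fixed on that haplotype therefore has an
expected read frequency of 0.5 in the heterogametic pool and ~0 (error
only) in the homogametic pool.

### Site classification

For every variable site passing the depth filter, each allele with a
nonzero combined count is evaluated independently:

* **XY-patterned**: frequency `< 0.1` in the female pool and within the
  closed interval `[0.3, 0.7]` in the male pool;
* **ZW-patterned**: the mirror image.

The `[0.3, 0.7]` band brackets the 0.5 expectation and absorbs binomial
sampling noise at realistic depths; the strict `< 0.1` bound tolerates
sequencing error and rare recombinants while excluding genuinely
polymorphic sites. We read "between 0.3 and 0.7" as the closed interval
and "less than 0.1" as strict so boundary behaviour is testable; both
thresholds (`t_fix`, `t_lo`, `t_hi`) are arguments of
`classify_sites()`. At a multi-allelic site each alternate allele is
evaluated on its own, but a site contributes at most one XY and one ZW
record (highest FST wins), so window counts cannot be inflated by allele
bookkeeping.

### Per-site FST

Pool differentiation is summarised by Wright's fixation index computed
from the two pool frequencies with equal pool weights,

$$F_{ST} = \frac{H_T - \bar H_S}{H_T}, \qquad H = 2p(1-p),$$

defined as 0 when $H_T = 0$. No sequencing-error or finite-pool
correction is applied: the statistic is used as a visual scan track and a
per-allele ranking, not as an unbiased estimator of population
differentiation. It is symmetric, 0 for identical pools and 1 for a fixed
difference; for example a (0.5, 0) contrast gives exactly 1/3.

### Depth filter

Sites need at least `min_depth = 4` reads in *each* pool; below that, the
frequency bins above are meaningless. Zero-depth sites are always
skipped. Skips are logged with reasons (`zero_depth`, `low_depth`,
`not_variable`) so input/output accounting is auditable.

## The windowed scan

Sex-patterned SNPs are aggregated in non-overlapping 100-kb tiles
(0-based half-open, the BED convention; site TSVs stay 1-based). Exactly
`ceiling(0.01 * N)` of the N anchored windows are flagged as the top 1%
by sex-patterned SNP count, with ties broken deterministically by
`(chrom, start)` — reproducibility over elegance. Unanchored contigs are
tiled and counted but excluded from the denominator, mirroring the
practice of remapping unplaced signal onto a more contiguous assembly
rather than letting it dilute the genome-wide quantile.

Each window gets a `log2((n_XY + c) / (n_ZW + c))` ratio with
pseudocount `c = 1` in both numerator and denominator, keeping every
window finite and the statistic antisymmetric under XY/ZW exchange. The
ratio is computed for **all** windows (not only the top 1%) before the
rank tests. Heterogeneity among chromosomes is tested with the
Kruskal-Wallis rank test (tie-corrected, chi-square approximation,
`k - 1` df; the all-tied degenerate case is defined as H = 0). When it
rejects, Dunn's pairwise post hoc test follows, using the pooled
tie-corrected rank variance
$N(N+1)/12 - \sum(t^3 - t)/(12(N-1))$, with Benjamini-Hochberg
adjustment of the two-sided p-values. Dunn's test is implemented in the
package (and cross-checked in the test suite against a brute-force rank
oracle) rather than taken from a dependency.

### The automated sex-system call

The published analyses decide heterogamety by inspecting the top-window
table; `call_sex_system()` automates that with three explicit, exposed
rules:

1. **Background guard.** A top window *supports* a call only if its SNP
   count reaches `max(min_snps, qpois(1 - 1e-4, lambda) + 1)`, with
   `lambda` the median window count — a Poisson tail bound on background
   misclassification. With no supporting window the call is `none`.
2. **Plurality.** The chromosome holding the most supporting windows is
   the candidate; if it holds less than 10% of them, the call is `none`.
3. **Majority.** If more than 2/3 of the candidate's supporting windows
   have `n_XY > n_ZW` the call is `XY`; the mirror gives `ZW`; otherwise
   `mixed` (both signals on one chromosome is a real, observed pattern).

These three thresholds are package inventions, chosen once to reproduce
clear-cut calls on synthetic analogues of the published cases, and are
arguments rather than constants.

## Sex-specific k-mers

Whether two syntenic sex systems share one origin is asked at the
sequence level: a shared sex-limited haplotype leaves thousands of
identical sex-specific k-mers in both populations, while independently
evolved systems share essentially none. `count_kmers()` tabulates
canonical 22-mers (lexicographic minimum of a k-mer and its reverse
complement, so counting is strand-agnostic; windows containing `N` are
skipped). The tabulation is a plain in-memory implementation intended
for simulated pools and desk-scale references — use a dedicated k-mer
counter for full sequencing runs.

A k-mer is **sex-specific** when it appears at least `min_count = 2`
times in the focal pool and never in the other pool; singletons are
dominated by sequencing error, and the test suite demonstrates the leak
that `min_count = 1` admits. Cross-population comparison is an exact set
intersection (pairwise by default; intersect repeatedly for an
all-populations list). Placement on a reference is by exact canonical
match at every locus, with an optional single-mismatch mode via
neighbour enumeration; at k = 22 an exact match is already a stringent,
dependency-free stand-in for aligning short perfect queries.

## Recruitment statistics

Counts of independent sex chromosome origins per linkage group (the
bundled table: 51 events over 23 categories, the 22-chromosome karyotype
plus the B chromosome) are fitted with a Poisson:

* `poisson_mean()` — events per category (51/23 ≈ 2.22);
* `poisson_expected()` — expected number of chromosomes per occurrence
  class, with an absorbing tail class so expectations sum exactly;
* `chisq_gof()` — chi-square goodness of fit. Occurrence classes are
  pooled from the top until the expected count reaches `pool_min = 1`,
  and `df = bins - 2` (one df for the estimated mean). The published
  analysis does not state its binning, so the exact p-value depends on
  policy; this package documents its policy, reports statistic, df and
  p together, and its tests assert only the non-rejection conclusion.

`monte_carlo_recruitment()` asks whether particular chromosomes are
recruited more often than chance once size is accounted for: each of
`n_reps` replicates drops `n_events` events on chromosomes with
probability proportional to length, and the raw p is the proportion of
replicates in which the focal chromosome is hit at least as often as
observed, Bonferroni-multiplied by `n_tests` (2 when testing LG5 and
LG7). The plain proportion is used — it keeps p = 1 exact for an
observed count of 0 — with the `(r+1)/(n+1)` estimator behind
`add_one = TRUE`. A seed is mandatory; the same seed gives bitwise
identical p-values.

Because the focal count is discrete, the plain tail p-value is
*super-uniform* under the null (conservative, with jumps the size of
point masses), so a distributional check of p itself against U(0,1)
would reject for any correct implementation. The calibration test in the
suite therefore applies the standard randomised probability integral
transform, $u = P(X > x) + U \cdot P(X = x)$, computed from the same
Monte Carlo replicates, which is exactly uniform when the generator and
the test agree.

The B chromosome is a category only if given a size; the bundled size
table assigns it the mean chromosome size and leaves it unanchored.
Both inclusion modes are one `sizes` argument away.

### Turnover rates

`turnover_rate()` divides the number of observed turnovers by a summed
branch length, typically from `sum_branch_lengths()` on a time tree in
MY. Pruning to a subtree keeps only edges *within* the clade: the stem
becomes the pruned tree's root edge and is excluded. Turnover counts are
inputs — the package does no ancestral-state reconstruction. The bundled
nine-tip tree is synthetic, calibrated so the full tree sums to 26 MY
and the seven-population *Pseudocrenilabrus* subtree to 10 MY; with 6
and 4 turnovers these give ≈0.23 and 0.40 turnovers/MY.

## The synthetic-data generator

`simulate_pooled_counts()` emulates exactly the features the scan
exploits:

* background SNPs with one population frequency per site (uniform on
  `[0.05, 0.95]`, a plain stand-in for the common variants a pool-seq
  discovery panel retains) sampled in two stages — binomial over the
  `2N` pooled chromosomes of each sex, then binomial reads at Poisson
  depth — so both finite-pool and finite-depth noise are present;
* sex-linked sites whose linked allele rides the sex-limited haplotype,
  at `0.5 * system_frequency` expected frequency in the heterogametic
  pool; `system_frequency < 1` emulates a system segregating at reduced
  frequency, which visibly thins the sex-patterned SNP signal;
* strata of differing sex-linked SNP density within the region;
* uniform substitution error at `error_rate = 0.002`, enough to exercise
  the `< 0.1` "fixed" threshold and the k-mer singleton guard.

Defaults are 25/24 individuals per pool, 50x mean depth, 1 background
SNP per kb and 1 sex-linked SNP per kb in the planted region (i.e. ~100
per 100-kb window, mid-range between the sparsest and densest systems a
scan encounters). The generator does **not** model linkage
disequilibrium, recombination suppression history, coalescent structure,
mapping bias or indels — so passing tests show the *statistical
machinery* recovers planted signal under honest sampling noise, not that
every real dataset with these settings would behave as cleanly.

`simulate_pool_sequences()` builds pool sequence sets for the k-mer
stage, either with the sex-limited sequence as a standalone contig (its
specific k-mer count is then analytically `L - k + 1`, e.g. 979 for a
1-kb insertion at k = 22) or embedded in a reference chromosome so
placements land back on the region. Passing one population's result as
`template` to a second re-uses the sex-limited sequence identically —
identity by descent — while redrawing the background, which is the
shared-origin contrast the k-mer analysis is designed to detect.

`simulate_recruitments()` draws recruitment tables from the
size-weighted multinomial null for calibration studies.

## Numerical and scale choices

* Windows, positions and BED outputs follow their format standards;
  internal window assignment is by `findInterval` on 0-based starts and
  is oracle-tested against explicit tiling.
* All generators and the Monte Carlo require a seed; no function draws
  from an unseeded RNG.
* Degenerate inputs are defined, not special-cased ad hoc: FST with
  $H_T = 0$ is 0, an all-tied Kruskal-Wallis is H = 0, an all-zero
  window table still yields a deterministic (warned) top set, a
  zero-depth site is skipped with a logged reason.
* The test suite runs at desk scale by design: simulated genomes of
  3 x 5 Mb for end-to-end recovery (20 planted plus 10 null datasets),
  10-kb sequences for k-mer oracles, 10,000 Monte Carlo replicates for
  the recruitment test and 500 simulated tables for its calibration.
  These sizes are the package's validation conditions; real analyses
  simply pass bigger inputs.

## Known limitations

* FST is a scan statistic here; no unbiased pool-seq estimator (e.g.
  depth-corrected) is provided.
* Evolutionary strata are emulated in simulation but not *inferred*
  from real data; delineating them remains a by-eye task.
* The k-mer stage is desk-scale and in-memory; real pools need an
  external counter, after which the set operations here apply
  unchanged.
* The automated call rules (background guard, plurality, majority) are
  reasonable defaults, not fitted constants; unusual architectures --
  several co-segregating systems, very low system frequency -- warrant
  inspecting the window table directly.

```{r example, eval = FALSE}
# A complete synthetic round trip:
genome <- c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6)
sim <- simulate_pooled_counts(
  genome, sex_system_spec("chr2", 2e6, 3e6 - 1, "XY"), seed = 42)
scan <- sex_scan(sim$counts, genome)
scan$call$chrom         # "chr2"
scan$call$heterogamety  # "XY"
```
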