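---
title: "Inferring copy number from allele balance, and differentiation in mixed-ploidy populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring copy number from allele balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abploidy)
```

## The signal: allele balance at heterozygous sites

At a heterozygous site, the fraction of sequencing reads supporting each
allele — the *allele balance* — is governed by allelic dosage, and dosage
by copy number. A diploid heterozygote carries one copy of each allele, so
both are sequenced at an expected frequency of 1/2. A triploid
heterozygote carries its alleles in a 2:1 ratio and is read at 2/3 and
1/3; a tetraploid at 3/4 and 1/4 (or 1/2 and 1/2 for the balanced 2:2
configuration); a pentaploid at 4/5 and 1/5. Summarizing the balances of
many heterozygous genotypes therefore reveals the copy number of a genome
— and, done in windows along a chromosome, of sub-genomic segments
(aneuploidy, segmental gains and losses).

`abploidy` implements this inference from standard VCF input (GT plus the
AD per-allele read depths emitted by callers such as GATK
HaplotypeCaller), together with allele-count-weighted differentiation
statistics for populations whose members may differ in copy number, and a
synthetic VCF generator with a known ploidy track so that every stage can
be validated end to end without any external data.

## Pipeline and parameters

```{r pipeline}
vcf <- system.file("extdata", "mini_synthetic.vcf", package = "abploidy")
v <- read_vcf(vcf)                                   # GT + AD string matrices
depths <- ad_to_depths(v$geno$AD, v$geno$GT)         # het-only (d1, d2)
depths <- censor_by_depth(depths, 0.05, 0.95)        # trim coverage tails
bal <- depths_to_balance(depths)                     # dominant + secondary
wp <- window_peaks(bal$dominant, v$variants$pos, v$variants$chrom,
                   window_size = 10000, bin_width = 0.02, min_count = 10)
calls <- assign_copy_number(wp$peaks)
table(calls$copy_number)
```

The stages, and the choices behind them:

**Heterozygote masking.** Only heterozygous genotypes are informative;
`is_het()` masks the rest. Phase separators `/` and `|` are treated
identically — the method never uses phase. A half-missing genotype such as
`./1` exposes a single allele class and is classified non-heterozygous. At
multiallelic sites the two most abundant alleles are kept (`ad_to_depths()`
takes the two largest AD entries), because the balance statistic is defined
on the top two alleles; the rare third allele at a genuinely polymorphic
site is treated as noise.

**Depth censoring.** Genotypes with unusually low or high total depth sit
in the long coverage tails (repeats, collapsed paralogs, dropout) and
distort the balance histogram. `censor_by_depth()` removes, per sample,
genotypes whose total depth falls outside empirical quantiles (default
0.05–0.95) of that sample's non-missing totals. Censoring is per sample
because samples differ in coverage. It runs *after* heterozygote masking,
so the quantiles describe the heterozygous site set actually analyzed.
The 0.05/0.95 defaults trim both tails symmetrically; they are exposed as
parameters because the appropriate trim depends on the coverage
distribution of each data set.

**Windowing and peak calling.** `window_peaks()` tiles each chromosome
with fixed windows anchored at position 1 (so windows are comparable
across samples regardless of where their variants happen to start),
histograms each window's balances in bins of width `bin_width`, and
reports the most occupied bin's midpoint as the window peak. Defaults:
`window_size = 40000` bases, appropriate for a yeast-like heterozygosity
of a few variants per kbp; `bin_width = 0.02`, small enough that the
1/3-vs-1/4 gap (1/12 ≈ 0.083) spans four bins; `min_count = 20`, below
which a mode is too noisy to trust and the window reports its count but no
peak (this is how runs of loss of heterozygosity are censored). All three
interact with the study system — denser heterozygosity supports smaller
windows — and all are exposed.

Numerical details fixed for determinism: bins are half-open `(lo, hi]`, so
a balance of exactly 1/2 falls in the bin ending at 0.5 and an exact 0
(impossible for a true heterozygote) falls in no bin; bin membership uses
a relative tolerance of 1e-9 so edge values bin deterministically; a tie
between equally occupied bins resolves to the bin nearest 0.5 (biasing
toward the most common, diploid, state) and then to the lower bin. The
peak is the bin midpoint, which bounds the discretization error by
`bin_width / 2`.

**Copy-number assignment.** `assign_copy_number()` maps peaks to the
expected ratios 1/5, 1/4, 1/3, 1/2, 2/3, 3/4, 4/5 (copy numbers 5, 4, 3,
2, 3, 4, 5) using critical values halfway between adjacent expectations.
Confidence is the *distance from expectation*:

dfe = |peak − expectation| / (gap from that expectation to the flanking
critical value on the side where the peak lies),

which is 0 exactly on an expectation and 1 halfway between two. Because
the gaps flanking each expectation are symmetric, this single definition
covers both sides. `filter_copy_calls(calls, max_dfe)` optionally removes
border cases; no filtering is applied by default, since any threshold is a
study-level choice.

Two deliberate design points. First, peaks outside [0.175, 0.825] — one
half-gap (1/40) beyond the extreme expectations — return no call: such a
peak is closer to homozygosity than to any supported ratio, and ratios
beyond 4/5 (copy number > 5) are not modeled. Second, a peak exactly on a
critical value is assigned to the neighboring expectation nearer 1/2
rather than by a fixed interval closure; dfe = 1 there either way, and
this keeps calls exactly symmetric under `peak -> 1 - peak`, which an
asymmetric interval rule would violate.

**A known ambiguity.** A dominant-balance peak at 1/2 is called copy
number 2, yet 1/2 is also the central expectation of a balanced (2:2)
tetraploid. The modal bin alone cannot distinguish these; the 1/4 / 3/4
side peaks of a tetraploid are the discriminating signal, which is why the
secondary-balance matrix should be windowed alongside the dominant one and
inspected (e.g. with `plot_window_peaks()`).

## Differentiation in mixed-ploidy populations

Heterozygosity-based differentiation extends naturally to populations of
arbitrary and mixed copy number, because gene diversity depends only on
allele frequencies. `count_alleles()` lets every non-missing allele in
every genotype — whatever its ploidy — contribute one count. Populations
are then weighted by the number of alleles observed at each variant,
`w_k = n_k / Σ n`, which corrects simultaneously for unequal sample sizes
and for copy-number differences (a tetraploid sample carries twice the
allelic information of a diploid one). Weighting is per variant, since
missingness makes the observed counts vary site by site.

With per-population gene diversity `Hs_k = 1 − Σ_i p_ki²`:

* weighted `Hs = Σ_k w_k Hs_k`; pooled `p̄_i = Σ_k w_k p_ki`;
  `Ht = 1 − Σ_i p̄_i²`; Nei's `Gst = (Ht − Hs) / Ht`;
* `Htmax = 1 − Σ_k w_k² (1 − Hs_k)` — the total diversity if the
  populations shared no alleles. Substituting disjoint allele sets into
  the `Ht` formula gives `1 − Σ_k w_k² Σ_i p_ki²`, which is this
  expression; with equal weights it reduces to Hedrick's
  `HT(max) = (k − 1 + Hs) / k`;
* `Gstmax = (Htmax − Hs) / Htmax` and Hedrick's standardized
  `G'st = Gst / Gstmax`.

Monomorphic variants (`Ht = 0`) return `NA` rather than 0 for the ratio
statistics — absence of variation is not evidence of absence of
differentiation. Statistics are reported per variant; genome-wide
summaries (e.g. ratio-of-averages versus average-of-ratios) are left to
the analyst, who can aggregate the returned data frame however the study
requires. `gst_stats()` exposes the same formula layer directly for use
with summary inputs.

```{r gst}
gst_stats(hs = c(0.42, 0.42), n = c(20, 40), ht = 0.46)
```

## What the simulator emulates — and what it does not

`simulate_vcf()` generates the data structure the method consumes:
heterozygous site positions uniform at a configurable density (default 5
sites/kbp); total depth negative binomial around a mean (default 100, size
10 — sequencing coverage is overdispersed relative to Poisson);
alternate-allele depth binomial at the true dosage ratio from a
piecewise-constant per-sample ploidy track; and a uniform-noise fraction
(default 0.05) of genotypes whose balance is uniform on (0, 1), mimicking
the broad histogram base that mapping artifacts and paralogs produce in
real data. Genotypes are written as diploid-style `0/1` calls, as a
diploid-model caller reports them regardless of the sample's true ploidy.
Output is deterministic given the seed, to the byte.

The simulator deliberately omits several features of real data: reads are
not simulated (no mapping error, no strand or reference bias, which in
real data shifts balances slightly toward the reference allele);
positions are uniform rather than clustered; sites are independent (no
linkage); depth is independent of position (no GC waves); and noise is a
single uniform component. Passing tests therefore demonstrate that the
windowing, binning, assignment and weighting machinery is correct under
the stated generative model — not that any particular organism's data will
be as clean. On real data the practitioner should expect broader peaks,
reference bias, and regions (LOH, repeats) where `min_count` censoring is
doing essential work.

`simulate_populations()` draws genotypes allele-wise from per-population
frequency vectors at each sample's own ploidy, providing ground truth for
the mixed-ploidy differentiation statistics.

## Problem sizes and verification

The test suite validates every stage against independent oracles:
brute-force loop-based binning and mode selection, hand-evaluated dfe
arithmetic, textbook Nei Gst on equal-ploidy data, and the worked
differentiation table recomputed from its printed inputs. Simulation-based
checks use one 1-Mbp chromosome at 5 het sites/kbp (5,000 variants, 25
windows of 40 kbp) with depth 100 and 5% noise — enough support (~200
variants/window) that a planted triploid segment is recovered window by
window, while the whole suite runs in well under a minute. At these
settings the dominant-peak separation between adjacent copy numbers (≥
1/12) is more than four bins, so recovery failures indicate logic errors,
not sampling noise.

## Limitations

* Copy numbers above 5 are not called; ratios like 1/6 are outside the
  expectation set.
* Balanced tetraploidy (2:2) is indistinguishable from diploidy by the
  dominant peak alone (see above).
* The method is histogram-based by design — no mixture model, no use of
  absolute depth. It trades statistical efficiency for transparency and
  robustness; integrating absolute coverage would be a natural extension.
* dfe is a confidence *ordering*, not a probability.
* Windows are fixed-width and anchored at position 1; the last window of a
  chromosome is reported at full width.
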