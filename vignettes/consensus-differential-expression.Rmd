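---
title: "Consensus differential expression for nested replicate-pooled designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression for nested replicate-pooled designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

comboDE targets a common but awkward bulk RNA-seq design: biological
replicates are *pools* of individuals (here 6-10 animals per pool), two pools
per sampling site, with sites nested inside a two-level condition of interest
— anciently versus recently invaded populations along an invasion route. The
contrast of interest (invasion category) lives at the *site* level, while
sequencing replication lives at the *pool* level, and pool-to-pool variability
within a site can be considerable. A naive two-group test across libraries
ignores this hierarchy and overstates its evidence; a site-level analysis
with four sites per category has little power. comboDE implements the
three-pronged strategy designed for exactly this structure, plus the
downstream enrichment statistics, and a simulator that reproduces the design
so every stage can be validated end to end.

## The model

Counts for gene $g$ in library $j$ are modelled as negative binomial,

$$c_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\ \phi_g\right), \qquad
\operatorname{Var}(c_{gj}) = \mu_{gj} + \phi_g \mu_{gj}^2,$$

with $\log \mu_{gj} = \log s_j + \log q_g + \ln 2\,(x_j \beta_g + u_{g,
\mathrm{site}(j)})$: $s_j$ an effective library size, $q_g$ a baseline
abundance, $x_j$ the invasion-category indicator (1 = recent), $\beta_g$ the
log2 fold change, and $u$ site-level random effects. Positive $\beta_g$
always means higher expression at recently invaded sites, in every table this
package writes.

### Normalization and filtering

Libraries are scaled by relative log expression (RLE) factors: the median,
over genes positive in all libraries, of the ratio of a gene's count to its
geometric-mean reference, rescaled to geometric mean 1. The effective library
size multiplies each size factor by the geometric-mean raw library sum. This
pairing is deliberate: the median-of-ratios factor already carries the
library's relative depth, so multiplying it by its *own* raw sum would count
depth twice (a library sequenced twice as deeply would get four times the
effective size and every downstream offset, CPM value and exact-test
pseudo-count would be distorted). Using the geometric-mean library sum keeps
the conventional factor values — a depth-doubled pair of libraries gets
factors $(1/\sqrt2, \sqrt2)$ — while making effective sizes proportional to
true depth, and matches the effective-library-size convention of the
widely-used count-model toolchain.

Genes with fewer than 10 reads in total are removed — *per analysis subset*.
Each of the 256 replicate selections refilters its own 8 libraries, and the
16-library analyses filter independently, so each analysis defines its own
gene universe. This mirrors how per-analysis gene totals differ in practice,
and genes absent from a combination simply count as not-detected there.

### Strategy 1: exhaustive replicate combinations ("4vs4")

With two replicate pools per site there are $2^S$ ways to keep one pool per
site ($2^8 = 256$ here). Each selection is a complete standalone analysis:
refilter, renormalize, re-estimate dispersions, test each gene with the NB
conditional exact test (below), and apply Benjamini-Hochberg within the
selection. A gene's *tally* counts the selections in which it reached
FDR < 0.05.

The exact test scales counts to a common effective size (pseudo-counts,
rounded half-to-even), sums them within each category, and conditions on the
total: the null distribution of the category-A sum given the total is the
convolution of the two NB group totals (equivalently, beta-binomial). The
two-sided p-value sums all outcomes no more likely than the observed one,
with a $1 + 10^{-12}$ relative tolerance for floating-point ties. The
implementation evaluates the conditional distribution on a window of ±50
conditional standard deviations (always containing the observed outcome);
the excluded tail mass is far below double precision. The simple common-size
rescaling is used rather than a full quantile adjustment; tests verify the
resulting null calibration directly.

### Strategy 2: nested fixed-factor GLM ("8vs8")

All 16 libraries enter a log-link NB regression with offsets
$\log(\text{effective size})$ and design intercept + invasion indicator +
three sum-to-zero site contrasts within each category — the only full-rank
parameterization that keeps the invasion effect estimable with sites nested
in categories (the 8 columns span exactly the 8 site means). The invasion
coefficient is tested by likelihood ratio against the reduced model without
it (df = 1). Fitting is IRLS with step-halving (deviance provably
non-increasing), at most 100 iterations, relative deviance tolerance
$10^{-8}$, and an honest convergence flag.

### Dispersion estimation

The common dispersion maximizes the summed per-gene *Cox-Reid adjusted*
profile likelihood (group means profiled out at each candidate $\phi$, with
the $-\tfrac12\log\det$ information adjustment per profiled mean), searched
on $\log\phi \in [\log 10^{-8}, \log 10]$ to tolerance $10^{-6}$. The
adjustment matters here: with 8 site means profiled from 16 libraries,
unadjusted ML underestimates $\phi$ enough to push null positive rates from
5% to above 15%. Gene-wise dispersions shrink toward the common value by
weighted likelihood — each gene's adjusted profile likelihood plus
`prior_df / residual_df` times the average gene's likelihood — evaluated on
a dispersion grid densified around the common value with parabolic
refinement of each gene's maximum. `prior_df = 0` returns per-gene MLEs;
large values collapse to the common estimate; the default 10 is a
conventional, deliberately mild prior for designs of this size. Bounds
$[10^{-8}, 10]$ cover any realistic biological coefficient of variation.

### Strategy 3: shared within-site correlation ("random effects")

On log2-CPM values (prior count 0.5, +1 on the effective size), a single
correlation between the two pools of a site, shared across genes, is
estimated: per gene, invasion-category means are removed and the intraclass
correlation $(\mathrm{MSB}-\mathrm{MSW})/(\mathrm{MSB}+\mathrm{MSW})$ of the
residual replicate pairs is computed, then pooled across genes on the
Fisher-z scale with a 5%-trimmed mean and clipped to $(-0.99, 0.99)$. The
ANOVA (intraclass) form is used rather than a plain Pearson correlation of
residual pairs because removing category means induces a known negative bias
($\approx -1/7$ with four sites per category) in the naive pairwise
correlation; the ANOVA form is centred at the true correlation under the
null. Each gene is then fitted by generalized least squares with 2×2
block covariance (off-diagonal $\rho\sigma^2$), whitened analytically into
scaled within-pair sums and differences. Residual variances are moderated by
empirical Bayes: a scaled-F distribution is moment-matched on the log
variances (closed form via a Newton inversion of the trigamma function), and
the moderated t uses the posterior variance $(d_0 s_0^2 + d s^2)/(d_0 + d)$
on $d_0 + d$ degrees of freedom. At $\rho = 0$ with moderation disabled the
statistic is exactly the ordinary equal-variance two-sample t across the 16
libraries (residual df 14); the often-quoted reduction to a t-test on site
means only emerges in the $\rho \to 1$ limit, where the within-pair
differences carry no information about the contrast.

### The consensus rule

A gene is consensus-DE when it is significant in the 8vs8 analysis **and**
its 4vs4 tally reaches $\lceil 0.85 \times 256 \rceil = 218$ of the 256
selections. The ceiling convention makes "more than 85%" and "at least 85%"
coincide at $N = 256$. Genes significant in *all* selections are flagged
`systematic_4vs4` separately, and the tally histogram of 8vs8-significant
genes — the diagnostic from which the 85% threshold was originally chosen —
is attached to every consensus table and drawn by `plot()`.

Why this combination works is visible in simulation. Site-level random
effects shift both pools of a site together, so every 4vs4 selection sees
them; but within a selection they act as extra between-site variance inside
each category, which the per-selection dispersion estimate absorbs, making
each 4vs4 run conservative. The 8vs8 GLM has the opposite failure mode: its
site terms absorb site means, but the invasion contrast is still judged
against pool-level noise, so site variance makes it anticonservative — no
fixed-effect model at library level can rescue a site-level contrast, a
point worth emphasizing because it is sometimes assumed otherwise. With
strong site variance (`site_sd = 1`) the 8vs8 model alone flags roughly 40%
of null genes while the intersection with the 218-of-256 rule flags none
(see the package tests), and the shared-correlation model stays calibrated
throughout because the correlation it estimates *is* the site variance.

### Enrichment and fold-change shifts

Overrepresentation of a gene set is tested with the one-sided hypergeometric
upper tail $P(X \ge k)$ on margins intersected with the background universe,
BH-corrected across terms; terms with no background gene are skipped. The
test is one-sided because the question asked is enrichment; a two-sided
Fisher option is exposed. The default background is the filtered-gene
universe, with the annotation or the DE set itself available as
alternatives. Fold-change distribution shifts (e.g. immune-annotated versus
all DE genes) use the two-sided Wilcoxon rank-sum test, exact when both
samples are ≤ 12 and tie-free, otherwise the tie-corrected normal
approximation with continuity correction.

## The simulator

`simulate_dataset()` draws the full design: 2 categories × 4 sites × 2 pools
(16 libraries), pool sizes uniform on 6-10 with sex counts split
floor/ceiling alternately, NB counts from the model above with log-normal
baselines, library factors and gene-wise dispersions, a planted DE fraction
with signed $|\mathrm{Normal}(\text{lfc}, \text{lfc}/4)|$ effects, and an
"immune" gene subset whose DE effects are shifted upward. All randomness
derives from one seed through fixed per-stage streams, so every intermediate
is reproducible bit for bit. Defaults (5000 genes, 5% DE at mean |log2 FC| 2,
site SD 0.25, dispersions log-normal around 0.1, baseline median 50
counts/library) were chosen once as a realistic spleen-transcriptome-scale
testbed with enough power for validation; they are conditions for testing
the machinery, not estimates of any real system.

What the simulator deliberately does *not* model: read-level noise or mapping
artefacts, gene-gene correlation, sex-specific expression (pool sex ratios
are metadata only), pooling-noise dependence on pool size, and
composition-driven normalization failure. Passing tests therefore certify
the statistical machinery under the stated model, not robustness to these
real-data phenomena. Site effects are gene-specific and independent by
default (`shared_site_effects = TRUE` collapses them to a per-library
scaling, which RLE normalization then removes — useful as a negative
control).

## Numerical choices and degenerate inputs

* Dispersion bounds $[10^{-8}, 10]$; estimates within $10^{-3}$ (log scale)
  of a bound snap to it.
* Exact-test ties resolved with a $1+10^{-12}$ relative tolerance; all-zero
  genes return p = 1 and log FC 0 and are flagged degenerate.
* Fold-change estimates guard zeros: the exact test adds a 0.5 pseudo-count
  per group, and the 8vs8 GLM reports log2 FCs from a prior-count-augmented
  fit (average prior 0.125 per library, scaled by relative library size)
  while testing on raw counts, so genes with an empty category keep finite
  fold changes.
* Medians use the midpoint convention; RLE requires at least one gene
  positive everywhere and fails loudly otherwise.
* BH is recomputed independently within every analysis (each selection, the
  8vs8 run, the random-effects run): each is a complete test set.
* Validation is total: malformed inputs raise classed errors
  (`comboDE_format_error`, `comboDE_design_error`, ...), never silent
  coercions.

## Problem sizes used in the test suite

The packaged tests exercise calibration at 5000 genes under the global null,
recovery at 2000-5000 genes, the full 256-combination consensus at 600-800
genes, and oracle equivalences (exhaustive enumeration, direct likelihood
maximization, pmf summation) at small n — sizes chosen so the whole suite
doubles as a practical regression harness while still resolving the rates it
checks. Independent implementations of the standard components (edgeR for
RLE/dispersion/GLM, limma for the correlation pipeline) serve as
cross-checks in the tests, not as the implementation.

## Known limitations

* The 8vs8 LRT is asymptotic; with 16 libraries its null positive rate sits
  near 0.055 rather than exactly 0.05 even without site variance.
* Exact-test p-values are discrete; uniformity holds only approximately at
  low counts, and goodness-of-fit tests that assume continuity (e.g.
  Kolmogorov-Smirnov) will reject on discreteness alone.
* No quasi-likelihood F-tests, trended dispersions, or precision-weight
  variance modelling; no TMM/upper-quartile normalization variants.
* One species at a time: cross-species contrasts are made by running the
  pipeline per species and comparing result tables
  (`compare_lfc_distributions()`).
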