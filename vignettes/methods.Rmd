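---
title: "Models and methods in pubpulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pubpulse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pubpulse` quantifies how GWAS associations redirect biomedical research
attention across human genes. This vignette explains the models and
procedures, the choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the known
limitations. It states no empirical result beyond what the package's tests
and acceptance script themselves compute.

## 1. Data model

The unit of data is a *publication history*: for a fixed gene universe and
a contiguous span of calendar years, an integer matrix of annual
publication counts plus a per-gene *baseline* of publications from before
the span. The cumulative count of gene $i$ through year $t$,
$P_{i,t}$, is the baseline plus the running sum; the cohort mean
$P^*_t$ averages $P_{i,t}$ over the **full universe including
zero-publication genes**. Fixing the universe from an explicit gene table
(rather than inferring it from the link table) is deliberate: genes with no
publications exist and carry rank 1 in the inequality analyses.

Publication years are attributed as the earliest of the record's reported
year and its electronic-publication year; links without any usable year are
dropped and counted. Pre-span publications are not discarded: they fold
into the baseline so cumulative sums stay exact, while the corresponding
gene-years stay out of the likelihood window.

## 2. Ingestion rules

* **Variant-to-gene mapping.** A variant maps to its closest gene when that
  gene lies within 500 kb, and to all genes whose bodies contain it when
  they overlap. Distance is 0 inside a gene body and otherwise base pairs
  to the nearer interval end; equidistant ties go to the smaller gene id so
  results are reproducible. Internally the search uses
  GenomicRanges/IRanges in their native 1-based closed convention — the
  library owns the interval arithmetic, which was the point of fixing a
  convention at all. A point query's `distance()` gap is one less than the
  bp separation, so the implementation adds one before applying the 500-kb
  rule.
* **Trait filtering.** Disease traits are defined by a caller-supplied term
  list (descendants of the disease root of the trait ontology). Ontology
  traversal is out of scope; supplying direct children instead of the full
  closure is the caller's choice through the same file.
* **Odds-ratio recognition.** The catalog's effect-size column mixes odds
  ratios and betas. A value is treated as an odds ratio only when a
  risk-allele frequency was reported and the confidence-interval text
  carries no unit annotation.
* **Gene classes.** Mendelian = OMIM-Mendelian only; complex = complex via
  OMIM-multifactorial or via GWAS, and not OMIM-Mendelian; both = both;
  none = otherwise. The first-GWAS year is the year of the earliest
  surviving association; its p-value and odds ratio come from the
  smallest-p association of that first year.

Every filter decrements a logged accounting vector, and the parsing tests
assert the accounting identity (rows in = links out + taxon-filtered +
duplicates + malformed + missing-year).

## 3. Inequality analysis

The Gini coefficient uses the population (denominator $n^2$) convention,
computed from the sorted form $G = \frac{2\sum_i i\,x_{(i)}}{n\sum_i x_i} -
\frac{n+1}{n}$, with zero-count genes included by default (an
`include_zeros` switch exists because the convention is not universal).
The Lorenz curve is built from ascending-sorted counts and its
trapezoid-area Gini agrees with the pairwise form within $1/n$ — both
facts are asserted against brute-force oracles.

Era comparisons split counts at a cutoff year (2005 default; 2007/2009 are
supported alternates). Publication ranks are ascending (rank 1 = fewest)
with ties broken toward the smaller gene id; the era rank-shift test ranks
genes within the full universe per era, restricts to the tested class, and
applies a two-sided Mann–Whitney U test (`stats::wilcox.test`, normal
approximation; an exact-permutation oracle covers small cases in the
tests).

## 4. Matched-control publication excess

For each gene first associated in year $t_0$ (with a complete follow-up
window inside the data), the control is the never-GWAS gene minimizing
$|P_{c,t_0-1} - P_{g,t_0-1}|$; ties are re-compared at $t_0-2, t_0-3,
\dots$ back to the first year, and genes still tied are all kept and
averaged. The implementation resolves ties lazily; an exhaustive
lexicographic search over full comparison sequences serves as the test
oracle. Design choices the source material left open:

* *Recent publications* are the 3 calendar years strictly before $t_0$.
  Excluding $t_0$ keeps the predictor clear of the outcome window.
* The normalization denominator $\sqrt{\max(\text{recent}, 1)}$ floors at
  one, keeping the statistic defined (and equal to the raw excess) for
  unstudied genes.
* Controls may serve several GWAS genes. Exclusive matching would make
  results depend on processing order.
* The candidate pool excludes genes that *ever* appear in the
  disease-filtered catalog, not merely before $t_0$.
* Association dates enter regressions as decimal years, at month precision
  when the catalog provides it, else mid-year.

The location test is a two-sided one-sample $t$ test of the normalized
excess against zero; predictor associations are tie-corrected Spearman
correlations; the joint model is OLS on log10(recent), −log10(p), odds
ratio and date, with an explicit error naming collinear columns on
rank-deficient designs. Optional robustness filters restrict to
high-confidence associations (p < 1e−8 and/or OR CI lower bound > 1.1),
and a half-year binned series totals the raw excess by association date.

## 5. The saturating Poisson rate model

Expected publications follow
$$\Delta P_{i,t+1} = \frac{k_1 P^*_t + k_2 P_{i,t} + k_3}
{1 + (P^*_t/P_S)^{\alpha}},$$
with all five parameters shared across genes: $k_1$ is field-wide momentum,
$k_2$ per-gene preferential attachment, $k_3$ the basal rate of a
never-studied gene (publications/year), and $(P_S, \alpha)$ the saturation
scale (cumulative publications) and sharpness. Annual counts are modelled
as independent Poisson draws with these means.

**Numerical choices.** The likelihood is maximized in log-parameter space
(bounds $[10^{-6}, 10^3]$) with analytic gradients under L-BFGS-B, from
one heuristic start plus log-uniform random restarts (5 starts by default,
seed-controlled), keeping the best converged optimum. Means are floored at
$10^{-10}$ so boundary parameters cannot produce $\log 0$ against a
positive count. Cohort means come from the full universe even when the
likelihood covers only never-GWAS genes — the training rule excludes GWAS
genes from the *fit*, while $P^*$ describes the organism-wide literature
(a config point, since the source is ambiguous). Degenerate inputs
(all-zero histories) drive the rate parameters to the lower bound and set
a `saturation_unidentified` flag instead of failing.

**Hot gene-years.** The scan compares each observed count to the model
mean through the upper Poisson tail $P(X \ge x)$, computed by the
survival function (regularized incomplete gamma machinery) rather than
$1 - \mathrm{CDF}$, so far-tail probabilities keep full precision. A
gene-year is *hot* when its tail probability falls below
$0.05/(N_g N_y)$; by default $N_g$ and $N_y$ are the universe size and the
number of scanned years. "Recent GWAS" means first associated within the
panel year or the two before it. The hot-gene logistic model regresses
hotness on log10(recent publications, floored at 1), calendar year
(centered at 2000 for conditioning; signs unaffected), the recent-GWAS
indicator and its year interaction. Perfect or quasi-perfect separation
raises an explicit error advising the ridge-stabilized fit — a Newton
solver with a small L2 penalty (intercept unpenalized) whose standard
errors come from the penalized information matrix; those are approximate
and the penalized path is a fallback, not the default.

## 6. The synthetic world

The generator *is* the stated world of the analysis, not a tuning knob:

* Annual counts are Poisson with the rate-model mean evaluated
  **self-consistently** on the realized counts and realized $P^*_t$ —
  matching how fitting later consumes data. The default configuration is
  5,000 genes, 1950–2015, the published maximum-likelihood parameters
  (k₁ = 0.0214, k₂ = 0.225, k₃ = 0.00288, P_S = 24.1, α = 1.67), no
  heterogeneity.
* Optional per-gene heterogeneity is a log-normal multiplier on the mean
  (mean-one parameterization). The shared-parameter model is the fitting
  assumption, so recovery tests use heterogeneity 0; the Gini of simulated
  totals rises monotonically with the heterogeneity SD (a tested
  invariant).
* GWAS shocks add independent Poisson(boost) publications in the
  association year and the following window − 1 years (window 3 by
  default). Additive boosting is the identifiable default; a
  multiplicative mode thins against realized counts for sensitivity
  checks. Declining-effect worlds use a boost linear in the association
  year, b(t₀) = max(12 − 0.7·(t₀ − 1996), 0) per window year — chosen once
  as a realistic decade-scale decay from ~12 extra publications/year to
  none.
* Association tables draw −log10 p uniformly on [5, 30] and odds ratios
  log-normal(0.15, 0.2) with symmetric log-scale CIs; a risk-allele
  frequency is always reported so re-ingestion recognizes the odds
  ratios. Null-world association eras (t₀ 2004–2012) and declining-world
  eras (1996–2012) mirror the real GWAS-catalog era.
* Fixture bundles round-trip exactly: parsing the written files reproduces
  the in-memory histories, classes and associations, and a rerun with the
  same seed is byte-identical.

**What the generator does not emulate:** persistent topical communities,
journals and impact factors, citation networks, author-level dynamics,
pre-span (pre-1950) publications, and the extreme empirical heavy tail in
which a handful of genes accumulate thousands of publications. A green
test therefore establishes correctness of the statistical machinery under
the stated Poisson world, not fidelity of that world to the real
literature.

## 7. Known limitations

* **Variance stabilization is imperfect at the bottom of the activity
  range in the homogeneous world.** Under shared parameters, a gene's
  realized recent count is a noisy proxy for its true rate: records with
  recent ∈ {0, 1} include genes whose window rate is dominated by the
  cohort term $k_1 P^*$, so after flooring the denominator their
  normalized-excess variance sits near $2\,\mathrm{E}[\lambda_{\rm win}]
  \approx 3$, while high-activity deciles shrink below 2 (given a large
  recent count, the true rate is typically smaller — regression to the
  mean). The decile-variance ratio therefore levels off around 2.1–2.7
  rather than below 2, and heterogeneous worlds widen it further. The
  qualitative contrast — raw-excess variance growing strongly with recent
  activity while the normalized variance stays within a factor of ~2–3 —
  holds and is tested; the strict "< 2×" bound is asserted as stated and
  currently fails, which the test suite reports honestly.
* The Mann–Whitney rank-shift test uses the normal approximation with tie
  correction; exact p-values are only used as oracles at tiny n.
* Penalized logistic standard errors are approximations from the
  penalized information matrix.
* $k_3$ is the hardest rate parameter to pin down at desk scale (its
  information comes from never-studied gene-years only); its median
  recovery error across seeds is ~8–9%, within but near the 10% recovery
  criterion.
* The pipeline assumes one association catalog snapshot; incremental
  updates or live retrieval are out of scope by design.
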