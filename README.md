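# pubpulse

Biomedical publications are distributed extremely unevenly across human
genes, and genome-wide association studies (GWAS) were expected to pull
research attention toward newly implicated, previously obscure genes.
`pubpulse` is an R package for quantifying whether that actually happens: it
measures publication inequality across genes, estimates the publication
*excess* a gene gains after its first GWAS association relative to a
matched control gene, and detects gene-years with exceptional publication
activity under a saturating Poisson rate model. A synthetic-data generator
reproduces the statistical structure of the real inputs (NCBI
gene2pubmed-style link tables, OMIM-style gene maps, GWAS-catalog-style
association tables), so the entire pipeline runs and is testable with no
downloads.

It is written for bibliometricians, statistical geneticists and anyone
studying research-attention dynamics over annotated entities with
count-valued activity histories.

## The statistics at the core

**Inequality.** Per-gene publication counts are summarized by Lorenz curves
and the population Gini coefficient
G = Σᵢⱼ |xᵢ − xⱼ| / (2 n² x̄), with zero-publication genes included, and
compared between the pre- and post-GWAS eras (cutoff 2005 by default).

**Matched-control excess.** Each gene first associated with complex disease
via GWAS in year t₀ is matched to the never-GWAS gene with the closest
cumulative publication count before t₀ (ties resolved year by year back to
the start of the data; remaining ties are averaged). The raw excess is the
gene's publications in years t₀…t₀+2 minus the control's; the normalized
excess divides by √(recent publications), the variance-stabilizing scale
under a Poisson publication model. Predictors (prior activity, association
p-value, odds ratio, association date) enter Spearman correlations and an
OLS regression.

**Rate model.** Expected publications for gene *i* in year *t*+1 follow

    ΔP_{i,t+1} = (k₁·P*_t + k₂·P_{i,t} + k₃) / (1 + (P*_t/P_S)^α)

where P_{i,t} is the gene's cumulative count, P*_t the cross-gene mean
cumulative count, k₁–k₃ rate parameters and (P_S, α) the saturation scale
and exponent. The five parameters are fitted by maximizing the Poisson
likelihood (L-BFGS-B in log-parameter space, analytic gradients,
multi-start). Gene-years whose observed count has a one-sided Poisson tail
probability below 0.05/(N_g·N_y) are flagged "hot", and hotness is modelled
by a logistic regression on recent activity, year, recent-GWAS status and
their interaction.

## Worked example

The `analysis/` directory is a numbered workflow over a synthetic world:
2,000 genes simulated from the published rate parameters
(k₁ = 0.0214, k₂ = 0.225, k₃ = 0.00288, P_S = 24.1, α = 1.67), with 150
GWAS associations between 1996 and 2012 whose publication boost declines
with the association year.

```sh
Rscript analysis/01_simulate.R    # world + input bundle -> results/world/
Rscript analysis/02_ingest.R     # parsers + filter accounting
Rscript analysis/03_inequality.R # Gini, Lorenz, rank shift
Rscript analysis/04_excess.R     # matched-control excess + regression
Rscript analysis/05_rate_model.R # ML fit, hot-gene scan, logistic model
Rscript analysis/06_report.R     # one-page summary
```

Stage 5 prints, for that world:

```
Fitted rate parameters (trained on never-GWAS genes):
      k1       k2       k3      P_S    alpha
 0.02169  0.22727  0.00290 23.63564  1.63727
Bonferroni cutoff 3.79e-07; 102 hot gene-years, 102 of them recent GWAS
Hot-gene logistic model (Table-2 shape):
              term estimate std_error  p_value
1      (Intercept) -12.8733     2.571 5.53e-07
2     log10_recent  -1.3648     0.292 3.03e-06
3             year   0.0673     0.185 7.15e-01
4      recent_gwas  14.1420     2.583 4.39e-08
5 year:recent_gwas  -0.4665     0.189 1.38e-02
```

The refitted parameters recover the generating values; the negative
year × recent-GWAS interaction recovers the injected decline of the GWAS
effect, and stage 4's regression shows the matching date coefficient
(−1.45, p ≈ 6e−47) on the normalized excess. The full summary lands in
`results/summary.md`.

## Acceptance script

`scripts/acceptance.R` recomputes the simulation-based headline quantities
from scratch with the installed package: it simulates 5,000-gene publication
histories (1950–2015) from the published rate parameters and refits the
model ten times, reporting the median fitted k₂, α, P_S and k₁, and it runs
the Bonferroni hot-gene scan over 200 null datasets (1,000 genes × 30
years), reporting the family-wise false-positive rate.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
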