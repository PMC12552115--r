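---
title: "Weighted rare-variant burden testing and predictor benchmarking with SLPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted rare-variant burden testing and predictor benchmarking with SLPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slpburden)
```

## The scientific problem

Many methods claim to predict whether a rare coding variant damages its
protein — conservation scores, protein-structure models, ensemble
classifiers, and lately DNA language models. A practical way to compare
them is to ask, for genes with established rare-variant phenotype
associations: *which predictor's scores, when used to weight a gene burden
test in a large case-control cohort, produce the strongest association
signal?* A better pathogenicity predictor concentrates weight on the
variants that actually drive risk, and therefore yields a smaller p-value
for the same gene, cohort and model.

`slpburden` implements that benchmarking pipeline end to end: consequence
classification, allele-frequency weighting, per-individual burden
aggregation, covariate-adjusted logistic association summarized as a signed
log10 p-value (SLP), and the multi-predictor comparison summaries. Because
the biobank-scale exome data this design targets is access-restricted, the
package also ships a synthetic cohort generator with a latent
true-pathogenicity variable, so every stage is testable and the pipeline's
statistical behaviour (type-I error, power ordering, effect recovery) can
be demonstrated on data with known ground truth.

## The model

For one gene, individual $i$ and a per-variant score $s_j$, the burden is

$$ b_i \;=\; \sum_{j \in \text{gene}} g_{ij}\, w(\mathrm{MAF}_j)\, s_j , $$

where $g_{ij} \in \{0,1,2\}$ is the ALT allele count and $w$ an
allele-frequency weight giving rarer variants more influence. Three kinds
of score are used: the LOF indicator (1 for stop-gained, frameshift and
essential splice-site variants), the protein-altering indicator (1 for
protein-altering, missense, start-lost and stop-lost variants), and one
column per pathogenicity predictor. Only rare variants
($\mathrm{MAF} \le 0.01$, inclusive) enter; variants in neither category
are excluded.

The association model for a binary phenotype $y_i$ is the logistic
regression

$$ \operatorname{logit} P(y_i = 1) = \beta_0 + \boldsymbol\gamma^\top
\mathrm{PC}_{i,1..20} + \gamma_s\,\mathrm{sex}_i + \beta_L b^{LOF}_i +
\beta_P b^{PA}_i + \beta\, b^{pred}_i , $$

and the statistic reported per gene × predictor is the signed log p-value
of the Wald test on $\beta$:

$$ \mathrm{SLP} = \operatorname{sign}(\beta)\,\bigl(-\log_{10} p\bigr),
\qquad z = \beta/\widehat{se},\; p = 2\Phi(-|z|). $$

Positive SLP means higher predictor-weighted burden associates with being
a case. For genes where damaging variants are protective, the outcome is
recoded as "being a control" before fitting (`flip_protective()`), which by
the exact symmetry of logistic regression under outcome complementation
negates the SLP; this keeps all expected signs positive and the per-gene
columns comparable. Repeating the fit for every predictor yields the SLP
matrix; its row means rank the predictors, per-gene division by the best
positive SLP gives the relative (dot-heatmap) scaling, and pairwise
correlations of the scores over missense variants describe how related the
predictors are.

### Score harmonization

Predictors arrive on incompatible scales, so three transforms put them on
a common "higher = more deleterious" footing:

* **DNA language-model log-likelihood ratios** (`transform_gpn_msa()`):
  distributed as $\log L(\mathrm{ALT})/L(\mathrm{REF})$, so the score is
  negated — a high transformed value marks an unlikely, hence likely
  deleterious, ALT allele.
* **AlphaMissense class labels** (`map_alphamissense_category()`):
  likely_pathogenic → 2, ambiguous → 1, likely_benign → 0.
* **Rank scores** (`rank_transform()`): the dbNSFP convention, rank /
  (number present) in $(0,1]$ with average ranks for ties; invariant to any
  strictly monotone rescaling of the raw score.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf_threshold` | 0.01 | inclusive rarity filter on MAF |
| `w_max` | 10 | weight at MAF = 0 (dimensionless multiplier) |
| `f_max` | 0.01 | MAF at which the weight reaches 1 |
| weight `form` | linear | $w = 1 + (w_{max}-1)(1 - \mathrm{MAF}/f_{max})$ |
| `n_pcs` | 20 | principal components in the covariate set |

The literature this design follows states only that rarer variants get
higher weights, without printing the curve; the linear form is the
package's default because it is the simplest curve with the stated
monotonicity and bounded range, and the `form` argument (step and logistic
alternatives) plus the metadata block in every output file keep the choice
explicit and revisable. Dosage counts homozygous ALT twice; missing
genotypes count as reference (the conservative burden-test convention) and
are tallied in a missingness report. Variants lacking a predictor's score
contribute 0 to that predictor's burden — LOF variants, for instance,
carry no missense scores, yet individuals still need defined totals.

## The synthetic cohort generator

`sim_config()` + `simulate_cohort()` generate data with exactly the
structure the analysis assumes. All distributional choices are this
package's own (the benchmarking design was built for real exome data and
implies no generative model); they were fixed once, on the following
rationale, and the same defaults are used everywhere including the
acceptance checks:

* **MAF law**: log-uniform on $[1/(2n),\ 0.01]$ — a crude but serviceable
  stand-in for a rare-variant site-frequency spectrum (density
  $\propto 1/f$), without population-genetic machinery. The lower bound is
  the minimum observable frequency; for very small test cohorts it is
  clamped to the upper bound.
* **Categories**: (LOF, protein-altering, excluded) = (0.1, 0.6, 0.3),
  roughly the proportions seen among rare exonic variants once
  non-qualifying classes are folded into "excluded".
* **Latent truth**: each variant carries a true pathogenicity
  $\sim U(0,1)$. A predictor of informativeness $\lambda$ scores variants
  by the quantile rank of $\lambda\,\mathrm{truth} +
  (1-\lambda)\,\mathrm{noise}$: $\lambda = 1$ reproduces the truth ordering
  exactly, $\lambda = 0$ is pure noise. Scores attach to protein-altering
  variants only by default (mirroring missense-specific predictors);
  `attach_to` widens this.
* **Genotypes**: independent Binomial(2, MAF) — Hardy–Weinberg at linkage
  equilibrium. No LD is simulated because the burden statistic sums
  variants within a gene and makes no LD assumption.
* **Phenotype**: logistic in the frequency-weighted *true* burden
  (effect 0.3 log-odds per burden unit by default) plus sex and 20 PCs;
  the intercept is found by root-finding so the expected prevalence hits
  the target (0.2 default) within $10^{-6}$. PCs are pure standard-normal
  noise: they exercise the covariate plumbing, deliberately not modelling
  stratification.
* **Seeding**: one master seed; per-component streams (variants, panel,
  genotypes, covariates, phenotype) are derived as
  $(7\,\mathrm{seed} + k) \bmod (2^{31}-1)$, so identical configurations
  give bit-identical outputs and any component can be regenerated alone.

What passing tests on this generator do **not** show: robustness to LD,
population stratification, relatedness, case-control imbalance beyond the
simulated prevalence, sequencing artefacts, or miscalibrated annotation —
all present in real exome data and all outside this generator's scope.

## Numerical choices

* Logistic fits use binomial IRLS with deviance tolerance $10^{-8}$, at
  most 100 iterations, and an explicit convergence flag; non-converged
  fits report `NA` SLP unless explicitly permitted, to avoid silently
  enormous values under separation. Exactly collinear columns are dropped
  and flagged.
* $|\mathrm{SLP}|$ is capped at 323 (the double-precision p-value
  underflow floor) with a flag; $\beta = 0$ exactly (measure zero, and the
  sign rule is undefined there) gives SLP 0, as does a degenerate
  constant-burden predictor.
* The Wald p uses the two-sided normal tail of $z=\beta/\widehat{se}$;
  the chi-squared parameterization of the same test gives an identical
  two-sided p.
* Outcome complementation negates fitted coefficients exactly in exact
  arithmetic; through finite IRLS the package's tests assert the SLP
  antisymmetry at $10^{-6}$ and affine invariance at $10^{-9}$.
* Correlations are Pearson by default (most inputs are rank scores, so
  Spearman is close; the choice is explicit, recorded in output metadata,
  and switchable), pairwise-complete because predictors cover different
  variant subsets, and masked to `NA` below 3 complete pairs.
* Test and acceptance problem sizes — 5,000 × 100 with 2,000 replicates
  for null calibration, 10 genes × 4,000 individuals for power ordering,
  100 replicates of 20,000 for effect recovery — were chosen as the
  smallest designs whose Monte-Carlo intervals make the checks sharp.

## Design decisions on open points

* **Disjoint categories**: a variant is LOF *or* protein-altering, never
  both; multi-transcript annotations take the most severe term
  (LOF > protein-altering > excluded).
* **MAF source**: the annotation table's MAF drives both filtering and
  weighting; computing MAF from cohort genotypes is possible upstream but
  the table is authoritative once written.
* **Whether predictors score splice-site variants** differs by predictor
  in practice; the generator makes it configurable (`attach_to`) and the
  burden code is indifferent (absent scores contribute 0).

## Known limitations

Firth or penalized regression for separation, mixed models, relatedness
correction and multiple-testing adjustment are out of scope — the design
reports raw SLPs. The comparison ranks predictors *on common-disease
gene-phenotype pairs in a cohort*; nothing here licenses extrapolation to
Mendelian-disease variant classification.

## A minimal run

```{r example}
cfg <- sim_config(n_individuals = 2000, n_variants = 100, seed = 42)
sim <- simulate_cohort(cfg)
prof <- gene_profiles(sim$genotypes, sim$variants, names(cfg$panel_spec))
predictor_slp(prof, sim$cohort, "informative", gene = "G001")
```

```{r reference}
ref <- slp_reference()
round(rowMeans(ref$slp), 2)[1:2]   # reproduces the published row averages
```
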