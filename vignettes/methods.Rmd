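---
title: "Methods: sex-specific age-related methylation remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific age-related methylation remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(2)
```

```{r setup}
library(methylSexAging)
```

# Scope

`methylSexAging` analyzes whole-blood DNA methylation array data (beta
values, the fraction methylated per CpG probe, in [0, 1]) across multiple
cohorts to characterize how methylation remodeling with age differs between
the sexes. It covers four analysis axes:

1. **saDMP discovery** — probes whose *mean* methylation associates with
   both sex and age, found by per-cohort correlation tests combined in a
   direction-aware meta-analysis.
2. **saVMP discovery** — probes whose *variance* grows or shrinks with age
   in one sex only (or in opposite directions), found by per-sex
   Breusch-Pagan heteroscedasticity tests.
3. **Epimutation burden** — per-subject counts of extreme outlier
   methylation values, modeled against age and sex.
4. **Methylome entropy** — a per-subject normalized Shannon entropy
   summarizing how disordered the methylome is, after removing
   cell-composition effects.

A synthetic multi-cohort generator with complete ground truth supports
validation of every stage without any cohort download.

# Statistical models

## Mean-level discovery (sDMP, aDMP, saDMP)

Within each cohort, betas are first residualized for nuisance covariates by
per-probe ordinary least squares (`regress_out()`): age plus the five
estimated leukocyte fractions (CD8T, CD4T, NK, B cells, granulocytes) for
the sex axis; sex plus cell fractions for the age axis. Each probe is then
scored by the Pearson correlation of the residuals with the target
(`associate()`); with sex coded F = 0, M = 1 this is the point-biserial
correlation, so "positive sex effect" always means *hypermethylated in
males*.

Per-cohort p-values are Benjamini-Hochberg adjusted within cohort, and the
adjusted values are combined across cohorts by a sample-size-weighted
Stouffer meta-analysis (`stouffer_meta()`):

$$z_i = \Phi^{-1}\!\left(1 - p_i/2\right)\cdot \mathrm{sign}_i, \qquad
  Z = \frac{\sum_i w_i z_i}{\sqrt{\sum_i w_i^2}}, \qquad w_i = \sqrt{n_i}.$$

Combining *adjusted* rather than raw p-values is deliberate: it makes each
cohort's contribution scale-free with respect to that cohort's probe count,
at the cost of conservatism. `call_dmps(use_bh = FALSE)` switches to raw
p-values.

A probe is called on an axis when its Bonferroni-corrected meta p-value
(over the common probe universe) is strictly below 0.01 **and** its
direction is concordant in every cohort; a zero sign (an exactly
zero-variance probe) breaks concordance. saDMPs are the intersection of the
sex- and age-axis calls; sex-only probes are snaDMPs (`classify_sadmps()`).
Each saDMP gets a quadrant label from the two meta directions
(M-hyper/M-hypo × age-hyper/age-hypo).

A complementary interaction scan (`interaction_scan()`) fits
`beta ~ age + sex + age:sex + cells` per probe and meta-analyzes the
interaction-term p-values the same way, catching probes whose *slope*
differs by sex even when the marginal effects do not reach significance.

## Variance-level discovery (saVMP)

Betas are residualized for cell fractions only, split by sex, and each
probe is tested for age-dependent variance with the classic
Lagrange-multiplier form of the Breusch-Pagan test (`bp_test()`): regress
the values on age, regress the squared residuals on age again, refer
$n R^2$ of the auxiliary fit to $\chi^2_1$. The auxiliary slope's sign is
retained as the direction of the variance trend.

Per-sex p-values are combined across cohorts by the unsigned
sample-size-weighted meta-analysis and Bonferroni-corrected. Scenarios
(`call_savmps()`):

- **female-specific**: female corrected meta p < 0.01 and male corrected
  meta p > 0.05;
- **male-specific**: the mirror image;
- **opposite**: both sexes significant with opposite, all-cohort-concordant
  variance directions.

The band between the two thresholds is a deliberate gray zone: a probe
whose "other" sex sits at p = 0.03 is neither clearly heteroscedastic nor
clearly homoscedastic, and no scenario is assigned. Both thresholds apply
to the *corrected* meta p-value, keeping the two criteria on the same
scale.

## Epimutations

For each probe the interquartile range of its beta distribution defines
outlier bounds $Q_1 - k\,\mathrm{IQR}$ and $Q_3 + k\,\mathrm{IQR}$ with
$k = 3$ by default; values *strictly* outside are flagged
(`detect_epimutations()`). Quartiles use the linear-interpolation
convention (R `quantile()` type 7). Per-subject counts are modeled as
`log10(count + 1) ~ age` per sex, plus a pooled ANCOVA with an age-by-sex
interaction (`burden_model()`).

## Methylome entropy

Betas are residualized for cell fractions, the probe mean is added back,
and values are clipped into $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 10^{-6}$ (`adjusted_betas()`); entropy requires values
strictly inside (0, 1) and the clip bound only affects probes already at
the numeric boundary. Per subject $j$ over $N$ probes:

$$H_j = \frac{1}{N \log(1/2)} \sum_{i=1}^{N}
  \left[\beta_{ij}\log\beta_{ij} + (1-\beta_{ij})\log(1-\beta_{ij})\right],$$

so $H = 1$ when every beta is 0.5 (maximal disorder) and $H \to 0$ as betas
approach 0 or 1. Note that entropy is a *concave* function of beta: purely
mean-preserving noise cannot raise its expectation. The age-related entropy
gain is driven by probe means drifting toward intermediate methylation, and
the synthetic generator reproduces exactly that mechanism (below).

```{r entropy-example}
m <- matrix(c(0.5, 0.11), 2, 1, dimnames = list(c("a", "b"), "S1"))
shannon_entropy(m)
```

## Enrichment

Probe catalogs are tested for enrichment against the post-filtering probe
universe with Fisher's exact test (`fisher_2x2()`, `probe_enrichment()`)
over CpG-island relation (Shore and Shelf pool their N/S flavors),
imprinted-region membership and hormone-pathway gene membership, plus
gene-level enrichment over the genes touched by at least one universe probe
(`gene_enrichment()`). The odds ratio reported is the sample OR
$(a d)/(b c)$; the conditional MLE that `fisher.test()` maximizes differs
negligibly at catalog scale. For tables whose minimum expected cell exceeds
1000, exact enumeration is replaced by an Edgeworth (skewness-corrected)
normal approximation to the hypergeometric tail with the minimum-likelihood
two-sided convention; the result carries `method = "approx"` and agrees
with enumeration to within a few percent in the regime where both run.

# The synthetic generator

`simulate_study()` draws a multi-cohort study from a shared probe truth
table (`probe_truth()`), so the same probe carries the same role in every
cohort — the premise of meta-analysis. Per cohort, sample ages are uniform
on the cohort's age range and sexes are balanced. Probe baselines are
bimodal (modes near 0.1 and 0.9 plus an intermediate band), matching the
familiar two-peak beta distribution of methylation arrays.

The per-sample mean is

`baseline + Δ·sex + b_sex·(age − midpoint) + λ·(Gran − E[Gran])`

with Gaussian noise whose SD can grow linearly with age
(`noise_sd · max(0.2, 1 + v_sex·(age − age_min))`), clipped to
[0.001, 0.999]. Age is centered at the cohort age-range midpoint, an
equivalent reparameterization that keeps baselines interpretable and
changes no slope or downstream statistic.

Key default parameters and their rationale:

| parameter | default | rationale |
|---|---|---|
| `cohort_sizes` | 4 × 500 | a four-cohort, blood-bank-scale meta-analysis |
| `n_probes` | 5000 | large enough for stable FDR estimates, small enough to simulate in seconds |
| `delta_sex` | 0.05 | a typical autosomal sex difference in mean beta |
| `age_slope` | 0.001/yr | ~0.07 beta over an adult lifespan, the common aDMP magnitude |
| `noise_sd` | 0.03 | typical residual probe SD in whole blood |
| `frac_sex/age/both` | 0.04 each | a few percent of probes carry each effect |
| `frac_het_male : frac_het_female` | 0.02 : 0.002 | the strong male excess among sex-specific variance trends |
| `het_slope` | 0.0125/yr | roughly doubles the SD across an adult age range |
| `cell_age_trend` | 0.005 | granulocyte fraction rising with age, the classic cell-composition confounder |

Age-effect slopes point **toward intermediate methylation** (positive below
baseline 0.5, negative above): epigenetic drift moves extreme probes toward
the middle, and with mid-range effect baselines this still produces a
near-even hyper/hypo split. This choice is what makes simulated entropy
rise with age.

Cell fractions are drawn Dirichlet-style with an age-trending granulocyte
concentration; the sample sheet carries *noisy estimates* of the true
fractions (SD 0.005), both because estimated fractions are what a real
pipeline sees and because exactly sum-to-one fractions would be collinear
with the intercept during residualization.

Epimutations are injected post hoc (`inject_epimutations()`): per subject a
Poisson count with rate `exp(base + age_coef · age)` of probe cells is
replaced by values beyond the detection bounds plus a safety margin, making
the injected truth unambiguous. Detection recovery is scored against the
*newly* flagged cells (flags on the contaminated matrix minus flags already
present on the clean matrix): Gaussian noise produces a ~3·10⁻⁶ per-cell
rate of natural 3·IQR outliers, which are genuine outliers of the noise
process rather than false positives of injection detection.

The generator does **not** emulate probe-level genomic autocorrelation,
batch effects, or array normalization artifacts.

```{r generator-demo}
cfg <- sim_config(cohort_sizes = c(150L, 150L),
                  age_ranges = list(c(20, 90), c(25, 85)),
                  n_probes = 400L, seed = 42)
study <- simulate_study(cfg)
table(study$truth$role)
```

# Numerical choices

- p-values are floored at 1e-300 before normal inversion, and tail
  quantiles are computed as `qnorm(p, lower.tail = FALSE)` rather than
  `qnorm(1 - p)` — for p below ~1e-17 the expression `1 - p` rounds to 1 in
  double precision and would yield infinite z-scores.
- Residualization uses a single QR decomposition of the design applied to
  the whole probe matrix, with a per-probe fallback only for probes with
  missing values; the interaction scan uses the same trick for per-probe
  coefficient t-tests. This keeps full-study scans in the seconds range.
- Quartiles use R's default type-7 (linear interpolation) convention
  throughout.
- Zero-variance probes get r = NA, p = 1, sign = 0 rather than an error;
  the zero sign then excludes them from any concordance-filtered call.

# Problem sizes used in the test suite

The package's own validation (see `tests/testthat/` and
`scripts/acceptance.R`) uses the generator defaults — four cohorts of 500
samples and 5000 probes — for the parameter-recovery checks (saDMP
sensitivity/FDR, saVMP scenario accuracy and sex-ratio), 2000 probes at
n = 500 for the Breusch-Pagan type-I-error check, 100 random 200×100
matrices for the epimutation brute-force equivalence, and two cohorts of
300 with 20% granulocyte-loaded probes for the confounding-removal check.
These sizes give each check enough power to be meaningful while keeping the
whole suite fast.

# Worked example

```{r pipeline, eval = FALSE}
dir <- tempfile(); dir.create(dir)
st <- simulate_study(sim_config(cohort_sizes = c(150L, 150L),
                                age_ranges = list(c(20, 90), c(25, 85)),
                                n_probes = 400L, seed = 42))
paths <- lapply(1:2, function(i) {
  b <- file.path(dir, sprintf("cohort%d.tsv.gz", i))
  s <- file.path(dir, sprintf("cohort%d.csv", i))
  write_beta_matrix(st$datasets[[i]], b)
  write_sample_sheet(st$sheets[[i]], s)
  c(beta = b, sheet = s)
})
ann <- file.path(dir, "annotation.tsv")
write_annotation(simulate_annotation(st$truth$probe_id, seed = 42), ann)

cfg <- run_config(vapply(paths, `[[`, "", "beta"),
                  vapply(paths, `[[`, "", "sheet"),
                  ann, seed = 1, out_dir = file.path(dir, "out"))
summary <- run_pipeline(cfg)
summary$counts
```

The same pipeline is available from a shell through the thin CLI installed
at `system.file("cli", "methylsexaging", package = "methylSexAging")`, with
subcommands `simulate`, `preprocess`, `dmp`, `vmp`, `epimut`, `entropy`,
`enrich` and `run-all`.
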