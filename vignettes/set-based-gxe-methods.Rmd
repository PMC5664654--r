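---
title: "Set-based gene-environment interaction tests for longitudinal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-based gene-environment interaction tests for longitudinal cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cohort studies of aging repeatedly measure quantitative outcomes such as
body mass index (BMI, kg/m²) while also collecting social and psychosocial
exposures — socioeconomic status in childhood and adulthood, anger, chronic
burden, stressful life events, social support, depressive symptoms. A
natural question is whether such exposures *modify* the effect of genetic
variation on the outcome. Testing each SNP × exposure interaction separately
is underpowered and multiplies the testing burden; aggregating all common
variants in a gene/region into one set-level test brings inference to the
gene level, which also travels better across ancestries than single-SNP
results do.

longGxE implements that workflow end to end for unbalanced longitudinal
panels (subjects contribute one or two exams here, but any cluster size is
accepted): exposure scoring and dichotomization, region construction around
GWAS index SNPs, GEE-based marginal tests, set-based score tests of
interaction and of the marginal genetic effect, meta-analysis across
ancestry strata, FDR control, and single-SNP follow-up.

## Model

For subject $i$ at exam $j$, with outcome $Y_{ij}$, covariates $X_{ij}$
(age, age², sex, optionally ancestry principal components), exposure
$E_{ij}$ (0/1, 1 = adverse), and time-invariant dosages
$G_i = (G_{i1},\dots,G_{ip})$ for the $p$ region variants:

$$Y_{ij} = \alpha' X_{ij} + f(E_{ij}) + \beta' G_i +
\gamma'(E_{ij} \cdot G_i) + e_{ij}$$

The interaction test is $H_0\!: \gamma = 0$. The marginal genetic test drops
the exposure terms and tests $H_0\!: \beta = 0$ in
$Y_{ij} = \alpha' X_{ij} + \beta' G_i + e_{ij}$.

Both are *score* (dispersion) tests built on a working-independence GEE fit
of the null model. Writing $\tilde S$ for the tested block (interaction
columns $E_{ij} G_i$, or the genotype columns themselves) residualized
against the null design, and $r$ for the null residuals, the score vector
accumulates per subject:

$$U = \sum_i \tilde S_i' r_i, \qquad Q = \sum_{k=1}^p w_k^2 U_k^2 .$$

Under $H_0$, $Q$ is distributed as $\sum_k \lambda_k \chi^2_1$ where
$\lambda_k$ are the eigenvalues of $W V W$, $W = \mathrm{diag}(w)$, and $V$
is the covariance of $U$. $V$ is estimated by the cluster-level empirical
("sandwich") covariance of the per-subject score contributions, which is
what makes the test valid under arbitrary within-subject correlation —
the working correlation is never trusted, only the subject-level clustering.

### Two ingredients that keep the null model honest

* **Spline exposure main effect.** A misspecified main effect of $E$ can
  masquerade as interaction. A binary exposure enters as one indicator (the
  spline degenerates); a continuous exposure enters through a cubic B-spline
  with `spline_knots` interior knots at quantiles (default 3). Our own
  acceptance suite reproduces the known failure mode: when the exposure is
  correlated with the region genotypes (gene–environment correlation 0.3)
  and its true effect is quadratic, the linear-only null rejects well above
  the nominal 0.05 while the spline null stays at or below 0.06 (2000
  replicates; `test-acceptance.R`, criterion 9). Notably, when genotypes
  are independent of the exposure the robust-variance test did not inflate
  in our pilots even under misspecification — the spline matters precisely
  when rGE is present, which is why the acceptance world includes it.

* **Weighted-PCA genotype main effect.** With many variants relative to the
  sample, adjusting for every SNP main effect destabilizes the null model.
  `weighted_pca_adjustment()` keeps the full standardized genotype block
  when $p \le p_{\max}$ (default $\min(100, n/10)$ — "revert to adjusting
  for all SNPs"), otherwise the fewest leading principal-component score
  columns reaching a fraction $\tau$ (default 0.95) of variance, carrying
  their natural $\sqrt{\text{eigenvalue}}$ scale. The exact construction
  used by the method's originating work is not fully specified in public
  sources; ours is a documented reconstruction and every knob is exposed —
  do not read the defaults as anyone else's settings.

### Finite-sample corrections (and why they exist)

The plain empirical sandwich is consistent but measurably miscalibrated at
realistic sizes. Two opposite failure modes appear:

1. With a large null design (covariates + spline + all-SNP adjustment), the
   residuals are shrunk toward zero in exactly the directions being tested,
   so $\hat V$ is biased downward and the interaction test over-rejects.
2. With a small null design, $\hat V$ is nearly unbiased but its
   *eigenvalues* are overdispersed (a Wishart-noise effect), the mixture
   tail is overestimated, and the marginal test under-rejects.

The defaults address both with standard, data-driven corrections:

* `correction = "kc"`: Kauermann–Carroll / CR2-type per-cluster residual
  adjustment $r_i \mapsto (I - H_{ii})^{-1/2} r_i$ in the meat, which
  removes the projection-induced bias. Cluster sizes 1 and 2 use closed
  forms, so this costs nothing.
* `shrink = "c2"`: the spectrum is shrunk affinely toward its mean
  eigenvalue with intensity chosen so $\sum_k \lambda_k^2$ equals the
  unbiased U-statistic estimate $\frac{n}{n-1}\sum_{i \ne j} (a_i'a_j)^2$
  of $\mathrm{tr}(V^2)$. No tuned constants; the intensity comes from the
  data. Structural zero eigenvalues (rank deficiency, e.g. duplicated
  variants) are excluded before shrinking, which preserves the invariance
  of the p-value under variant duplication.

With both corrections, both tests' null rejection rates at $\alpha = 0.05$
fall inside the binomial 95% band $[0.040, 0.060]$ in the 2000-replicate
null experiment the acceptance suite runs ($n = 500$, 58% two-exam,
$p = 30$, AR(1) LD 0.5, nonzero genotype and exposure main effects).
Both corrections are exactly the identity for the single-variant case,
where the test reduces
to the square of the familiar robust score $z$; `correction = "none",
shrink = "none"` recovers the textbook estimator and is what the
brute-force equivalence tests compare against.

### Mixture-of-chi-square tail probabilities

`quadform_pvalue()` offers a four-moment (Liu-type) noncentral-chi-square
approximation and Imhof-type characteristic-function inversion. The
inversion integrand lives on the scale of $1/\lambda$, so the spectrum is
rescaled to unit mean before integration — without this, generic quadrature
silently misses the oscillation and returns garbage for large-scale spectra.
The default (`"auto"`) uses moment matching and refines by inversion when
$p < 10^{-3}$, where moment matching is least accurate. Eigenvalues below
$10^{-10} \times \lambda_{\max}$ are truncated. Both routes agree with
$10^6$-draw Monte-Carlo tails within 5% relative error in the acceptance
suite.

## Exposure construction

Battery scoring follows fixed instrument rules (`hrs_battery()`): trait
anger (4 items, 1–4, averaged, missing if > 2 items missing), state anger
(7 items, > 3 missing), chronic burden (8 items, 1–4, summed), stressful
life events (6 yes/no items, summed), positive/negative social support
(3 resp. 4 reverse-coded items per relationship domain, averaged within
domain with > 1 resp. > 2 missing tolerated, domain scores averaged), and
an 8-item depressive-symptom count (two positively worded items
reverse-coded; range 0–8).

Dichotomization always codes 1 = adverse: median split within group pooled
over exams (ties to the reference side, matching "higher than the median"
labeling), zero-reference for counts, and education cut-offs for
socioeconomic status (childhood: either parent below a high-school degree,
strict `< 12`; adult: at most 12 years, `<= 12`). Decisions the sources
leave open, resolved here: social-support domains that are entirely missing
(no spouse) are skipped rather than propagating missingness; the outcome's
6-SD outlier rule computes mean and SD once on the pooled sample (not
iteratively) and is applied per stratum by the caller; the inverse-normal
transform uses Blom offsets $(r - 3/8)/(n + 1/4)$ with average ranks for
ties.

## Regions

A gene/region is the unbuffered span of a gene (transcripts merged to the
most inclusive start/stop) when the index SNP falls within the gene ± 5 kb;
otherwise a ± 50 kb window around the index SNP. Coordinates are 1-based
inclusive; "within 50 kb" means $|pos - index| \le 50000$. When several
genes contain the index SNP within buffer, a gene containing it unbuffered
wins, then the nearest boundary, then the alphabetically first id — the
sources never resolve this case, so the rule is ours and is deterministic
and annotation-order-invariant. Variant filters are strict: INFO > 0.5,
MAF > 0.01, position inside the span; a variant at exactly 0.5 or 0.01 is
excluded. Only biallelic SNVs are read from VCF input.

## The synthetic cohort

`sim_config()` states one world and the tests live in it; its defaults are
not moved to make tests pass. Structure: 500 subjects at desk scale
(full-size 7838 available by argument), 58.3% with a second exam 4 years
later (the observed two-exam share), age 66 (SD 10), 56.7% female, one
adverse exposure at prevalence 0.38 (the observed low-childhood-SES share),
60 common variants (MAF 0.05–0.5) with AR(1) copula LD 0.5 across a 100 kb
span, INFO = 1. The error is a subject random intercept plus white noise
(σ_b = 4.5, σ_e = 2.5), giving marginal SD ≈ 5.1 — near the observed 5.7 —
and within-subject correlation ≈ 0.76; a random intercept is the simplest
structure producing the exchangeable correlation the GEE machinery should
then recover. Genetic and interaction effects default to zero and are set
per experiment.

What the generator does *not* emulate: realistic LD beyond AR(1), allele
frequency spectra, missing genotypes, ancestry admixture, informative
dropout, measurement error in exposures. A green test therefore establishes
correctness of the statistical machinery under the stated covariance
structure, not robustness to everything real data does.

## Pipeline gating

`run_pipeline()` mirrors a staged discovery analysis: Stage 1 tests each
exposure's marginal association per stratum (GEE, exchangeable working) and
pools strata by inverse-variance meta-analysis, gating on Bonferroni within
the exposure family (α/9 → 0.0056 in the nine-exposure setup). Stage 2 runs
marginal set tests per region. Stage 3 runs interaction set tests only for
gated exposures, with Benjamini–Hochberg FDR applied within each
(stratum, exposure) family across regions — never across exposures — and
Fisher's method combining strata for exposures significant in the combined
meta. Stage 4 follows up FDR survivors with a single-SNP GEE scan and
covariate-adjusted genotype × exposure cell means (hard calls within ± 0.1
of an integer; independence working in the adjustment model so the adjusted
outcome is exactly orthogonal to the covariates). Every gating decision is
written to the log; all randomness flows through one seed recorded in the
manifest.

## Numerical and degenerate-input policy

Singular designs error, naming the collinear columns, except spline/
adjustment columns, which are dropped with a warning (the null model must
survive a constant exposure basis). Zero-variance variants are dropped with
a warning at standardization and skipped with a reason in the scan. A
region with no surviving variants is a warning plus an empty matrix; set
tests refuse empty blocks. Eigenvalue truncation and the Imhof rescaling are
described above. GEE convergence is declared at relative coefficient change
< 1e-8 (max 100 iterations); non-converged fits withhold their covariance.

## Known limitations

Gaussian identity-link outcomes only; fixed-effect meta-analysis only (no
heterogeneity statistics); no small-sample Wald corrections in the
single-SNP scan (sample sizes in the intended use are thousands); the
weighted-PCA adjustment is a reconstruction, not a reference
implementation; p-values below ~1e-12 are reported as computed by the
inversion but should be read as "very small" rather than exact.
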