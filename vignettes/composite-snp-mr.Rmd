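---
title: "One-sample Mendelian randomization with composite-SNP instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample Mendelian randomization with composite-SNP instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compositemr)
```

## The problem

Observational studies of older adults repeatedly find that moderate
overweight (BMI 25–30) is associated with *lower* mortality — the
"overweight paradox". Whether the association is causal is hard to settle:
unmeasured confounding (frailty, reverse causation from weight-losing
illness) can manufacture it. Mendelian randomization (MR) attacks the
question with genetics: because alleles are assigned at conception and
(given the usual assumptions) cannot be influenced by later disease, a
variant that raises BMI can serve as an instrumental variable (IV) for
overweight, and the variant–survival association then carries causal
information about overweight itself.

`compositemr` implements a one-sample MR pipeline for exactly this design:
exposure is overweight versus normal weight, defined from the average BMI
measured between ages 75 and 85 (overweight: mean BMI in [25, 30); normal:
[18.5, 25)); the outcome is survival to age 85 (1 if lifespan reached 85,
0 if death occurred earlier). Both variables are binary, and both
association sets are estimated in the same cohort.

## Composite SNPs

Candidate-gene MR studies face a bottleneck: among the limited number of
SNPs in biologically plausible genes (here eight obesity/BMI genes —
ADIPOQ, FTO, LEP, LEPR, INSIG2, MC4R, PCSK1, PPARG), few survive the three
IV assumptions. The package's central construction expands the candidate
pool by *pairing* SNPs: for two variants with minor-allele dosages
$d_a, d_b \in \{0,1,2\}$, the pair's summed dosage $d_a + d_b \in
\{0,\dots,4\}$ is recoded to a pseudo-genotype

$$
\mathrm{recode}(d_a, d_b) =
\begin{cases}
0 & d_a + d_b \le 1 \\
1 & d_a + d_b = 2 \\
2 & d_a + d_b \ge 3
\end{cases}
$$

and the resulting "composite SNP" is treated as an ordinary candidate
instrument — screened, pruned and fed to the estimators through exactly
the same code path as single SNPs (`recode_pair()`,
`build_composites()`). The recoding is the composite's *definition*, so
its coded-allele frequency is not re-aligned to the minor allele even when
it exceeds 0.5, and a missing constituent dosage makes the composite
missing. `m` single SNPs yield $\binom{m}{2}$ composites under the default
`all_pairs` scope; `between_genes` and `within_genes` scopes are also
exposed. We default to `all_pairs` because the construction itself is
agnostic to gene membership and the screening stage, not the pairing
stage, is where invalid pairs are meant to fall out.

## Instrument screening

`select_ivs()` screens every candidate against:

1. **Relevance** — the dosage must predict the exposure. Because the
   exposure is a dichotomized continuous trait, the association is
   required under *both* codings: logistic regression of overweight on
   dosage and linear regression of mean BMI on dosage, each at
   `alpha = 0.05`. The operational form of relevance is the
   instrument-strength criterion $F > 10$ with
   $F = \frac{n-k-1}{k}\,\frac{R^2}{1-R^2}$ and $k = 1$ per candidate.
   For unrelated samples $R^2$ is the Cox–Snell generalized $R^2$ of the
   logistic exposure fit divided by its attainable upper bound
   $1 - L_0^{2/n}$ (the max-rescaled / Nagelkerke correction)
   (`r2_for_unrelated()`, `f_statistic()`). For family samples the
   exposure is first fitted with a logistic mixed model (fixed covariates
   plus family random intercept via `lme4::glmer`); $R^2$ is then the
   squared correlation between the response residuals and the dosage,
   which is symmetric in the two variables, so the direction in which the
   simple regression is run is immaterial (`r2_for_related()`). If the
   mixed model fails to converge the fit falls back to a fixed-effects
   logistic model with a warning.
2. **Independence of confounders** — confounders are first *identified*:
   one logistic regression of the outcome on exposure plus all candidate
   covariates, keeping covariates with any significant coefficient
   (`identify_confounders()`). Each candidate instrument is then tested
   for association with each identified confounder (linear for
   continuous, logistic for binary, chi-square for multi-level
   categorical); any association fails the candidate.
3. **Exclusion** — regressing the outcome on dosage, exposure and the
   identified confounders, the dosage coefficient must *not* be
   significant; again under both exposure codings (binary overweight and
   continuous mean BMI).

Survivors are greedily pruned for linkage disequilibrium: while any pair
of retained candidates has squared dosage correlation $r^2 \ge 0.3$, the
member with the weaker exposure association (larger p) is dropped
(`ld_prune()`), with deterministic tie-breaks (pairs processed by
descending $r^2$, then lexicographic id; equal p removes the later id).
The screen emits a full audit trail — every candidate is labelled
`qualified` or `failed_*` with its statistics — so the "number of IVs"
entering each analysis is reconstructable.

Two open design points we resolved: the assumption-2 test regresses the
confounder on the dosage (the direction is unstated in the field's verbal
descriptions, and for the linear and chi-square tests the choice is
inconsequential); and no multiple-testing correction is applied across
candidates during screening (a Bonferroni option exists but is off by
default, matching common practice in candidate-gene screens).

## Estimators

Per qualified instrument $j$, `association_stats()` fits two univariate,
covariate-free logistic regressions in the retained cohort —
$\text{exposure} \sim \text{dosage}$ giving $(\hat\beta_{Xj}, s_{Xj})$ and
$\text{outcome} \sim \text{dosage}$ giving $(\hat\beta_{Yj}, s_{Yj})$ —
with pairwise complete cases per instrument. The estimator suite operates
on these summary statistics:

* **IVW** (`ivw()`): ratio estimates $\hat\theta_j =
  \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order delta-method standard
  errors $s_{Yj}/|\hat\beta_{Xj}|$ (a second-order option exists),
  averaged with weights $w_j = 1/\mathrm{se}(\hat\theta_j)^2$;
  algebraically identical to weighted least squares of $\hat\beta_Y$ on
  $\hat\beta_X$ through the origin.
* **Penalized IVW** (`penalized_ivw()`): each instrument's heterogeneity
  contribution $Q_j = w_j(\hat\theta_j - \hat\theta_{IVW})^2$ is mapped to
  its upper-tail $\chi^2_1$ probability $q_j$ and the weight downscaled to
  $w_j \min(1, 20\,q_j)$; reported when standard IVW is inconclusive
  (p ≥ 0.05), the situation it was designed for.
* **Weighted median** (`weighted_median()`): ratio estimates ordered and
  interpolated at 50% of cumulative weight; consistent when at least half
  the weight comes from valid instruments. Its standard error is a seeded
  parametric bootstrap (default 1000 draws of $\hat\beta_{Xj},
  \hat\beta_{Yj}$ from normals at their standard errors) — the defining
  publication's approach; no analytic se is attempted.
* **MR-Egger** (`mr_egger()`): weighted regression of outcome on exposure
  associations with a free intercept, instruments oriented so
  $\hat\beta_X \ge 0$; the intercept estimates directional pleiotropy and
  its 95% CI containing zero supports the exclusion assumption.
* **E-values** (`evalue()`, `evalue_summary()`): each instrument's odds
  ratio $e^{\hat\theta_j}$ is converted to a risk ratio and
  $E = RR + \sqrt{RR(RR-1)}$ summarized as (average, min, max). Because
  the outcome (survival past 85) is *common* (>50%), the default
  conversion is $RR \approx \sqrt{OR}$; the rare-outcome identity
  conversion is available.

`run_mr()` composes the suite, optionally per stratum (e.g. sex × race),
and attaches the significance verdict used throughout: IVW p < 0.05 *and*
Egger intercept CI covering zero. P-values and CIs are normal-theory
throughout, matching the CI construction. The result is a tidy object
with `tidy()`, `glance()`, `autoplot()` and `plot_mr_scatter()` methods.
One deliberately inert hook: in a one-sample design the exposure and
outcome statistics are correlated, and downstream consumers sometimes
adjust for the exposure–outcome association; the precise adjustment is not
standardized, so the option slot exists with default "none".

## The synthetic cohort generator

The real cohorts this design targets are access-restricted, so
`simulate_cohort()` generates cohorts with the same statistical skeleton
and *known* ground truth:

* genotypes per SNP: binomial(2, maf) in Hardy–Weinberg proportions, maf
  uniform in [0.1, 0.4] by default, 3 SNPs in each of the 8 candidate
  genes (independent draws; realistic LD structure is deliberately out of
  scope — pruning behaviour is tested on directly constructed correlated
  matrices instead);
* mean BMI over ages 75–85: baseline 21.75 kg/m² (the midpoint of the
  normal range, chosen so both exposure groups are well populated) plus
  additive SNP effects (`beta_main`, default 0.25 kg/m² per allele),
  optional SNP×SNP interaction effects applied to the *recoded pair
  dosage* (so composite instruments have a true signal to find), optional
  confounder contributions, an optional family-level random intercept,
  and Gaussian noise (sd 2.5 kg/m²);
* repeated measures: `n_bmi_measures` (default 3) per individual at ages
  uniform in [75, 85]; measurement noise around the individual mean
  defaults to 0 because no credible error magnitude is established for
  the target studies — it is a free knob;
* outcome: Bernoulli with logit = 1.1 + `theta_true`·overweight +
  confounder terms + optional direct SNP effects (`pleiotropy_effects`,
  the positive control for the exclusion test and the Egger intercept).
  The intercept 1.1 puts marginal survival near 75%, typical of such
  analysis samples, and `theta_true` defaults to 0.2;
* confounders act on *both* BMI and the outcome — that dual action is
  what makes them confounders — with cohort-characteristics-table-like default marginal
  frequencies for sex, race, education, smoking, comorbidity and field
  center, plus two standard-normal principal-component scores;
* ages: enrollment ~ N(67, 7) clipped to [50, 75.5]; deaths uniform in
  [76, 85), survivors censored uniform in [85, 95]. Exact ages only
  matter for the Kaplan–Meier display; the binary outcome is defined
  either way. Individuals with mean BMI outside [18.5, 30) are emitted
  and left for `derive_variables()` to exclude — filtering is analysis,
  not generation.

A single config seed drives one R random stream consumed in a fixed
order, so identical config + seed reproduces the cohort exactly;
`run_pipeline()` derives per-stage sub-seeds deterministically
(`seed + 1000003 × stage index`, mod 2³¹−1) so staged and monolithic runs
agree.

What passing tests on these cohorts do **not** establish: robustness to
real LD, to assortative mating, to population stratification beyond two
synthetic PCs, to informative missingness, or to BMI measurement error —
none of which the generator emulates.

## Variable derivation and edge cases

`derive_variables()` computes the mean of BMI measures whose measurement
age lies in the *closed* window [75, 85] (the boundary convention is ours;
colloquial "between 75 and 85" does not specify it), assigns exposure on
[18.5, 25) / [25, 30) half-open intervals, and outcome 1 iff lifespan
reached 85 (death at ≥ 85 still counts as surviving to 85). Individuals
censored alive before 85 have an unknowable outcome and are excluded with
reason `outcome_undetermined`; the other reason codes are
`no_bmi_in_window`, `bmi_out_of_range` and `missing_covariate`
(complete-case covariates). Exclusion is a flag plus report, never a
silent drop. Records with death before enrollment are rejected outright.

QC (`qc_filter()`) iterates variant call rate, individual call rate, MAF
and an exact Hardy–Weinberg test to a fixed point, which makes the filter
idempotent; with family data the HWE test is computed on one member per
family to avoid relatedness inflation. Default thresholds (call rates
0.95, MAF 0.01, HWE p 10⁻⁶) are configurable stand-ins for published
protocol values. Missing dosages are handled pairwise per instrument in
the association fits.

## Descriptive output

`descriptive_table()` reproduces a cohort-characteristics table per
sex × race stratum and overall. `kaplan_meier()` estimates survival past
75 by exposure group with *left truncation*: each individual enters the
risk set at max(enrollment age, 75), so a person enrolled at 80 does not
contribute person-time (or immortality) for ages 75–80. Individuals whose
event precedes entry are excluded with a reported count; an entry age
tied with an event age is treated as occurring just before it.
Confidence bands are log-log (exponential Greenwood) — a display choice;
no band type is canonical for this figure.

## Numerical choices and problem sizes

All heavy fits go through `glm.fit` with a separation guard (|slope| > 15
or se > 100 flags the instrument unusable rather than contaminating the
estimators). The test suite validates estimators against independent
oracles (weighted-least-squares-through-origin, direct interpolation of
the median, hand-rolled IRLS, exact Hardy–Weinberg enumeration, per-byte
PLINK decoding) and recovers planted effects at the generator's default
conditions; simulation-based checks run at n = 4,000–10,000 individuals,
100–500 replicates, and 15–30 instruments — sizes chosen to give
Monte-Carlo error comfortably below the tolerances being asserted.

One estimand subtlety documented rather than hidden: with a dichotomized
exposure and covariate-free logistic association statistics, the Wald
ratio does not converge to the conditional log-odds `theta_true` of the
generating model. The odds ratio is non-collapsible, and dichotomization
discards within-group exposure variation; the large-sample IVW value is
attenuated by roughly the factor $p_X(1-p_X)$, where $p_X$ is the
exposure prevalence. Estimator validation therefore measures bias and
coverage against the *estimand* (the large-sample value under the same
generative model, computed by a single large-n run), which is the
quantity the estimator can be consistent for. Interpretation of signs and
significance is unaffected; magnitudes on the `theta_true` scale are not
directly comparable.

## Known limitations

Two-sample MR, multivariable MR, outlier-search methods (MR-PRESSO),
colocalization, VCF input, non-integer dosages, sex chromosomes and
higher-order (triplet+) composites are out of scope. The GWAS mode is an
exposure-association *scan over supplied variants*, not genome-wide
tooling. Family-based inference is limited to the random-intercept
exposure model used for instrument strength.
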