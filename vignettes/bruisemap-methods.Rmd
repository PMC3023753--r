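---
title: "Methods: two-stage PK association mapping for tuber bruising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage PK association mapping for tuber bruising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bruisemap)
```

`bruisemap` implements a two-stage association analysis for
multi-environment trials of tetraploid potato clones scored for tuber
bruising and related traits, with dominant (presence/absence) DNA
fragments as markers. This vignette documents the statistical model,
the numerical choices, the design decisions taken where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Derived traits

A plot's bruising severity is summarized by the bruising index. Tubers
are visually scored into four discoloration categories (none, light,
medium, strong) and, with $L$, $M$, $S$ the fractions in the light,
medium and strong categories,

$$\mathrm{BI} = (0.3\,L + 0.5\,M + S) \times 100,$$

which ranges from 0 (no discolored tuber) to 100 (all tubers strongly
discolored). `compute_bruising_index()` works on counts and depends on
the category fractions only. Because bruising correlates strongly with
starch content, starch-corrected bruising (SCB) is defined as the
residual of the ordinary least-squares regression of BI on specific
gravity (SG). `compute_scb()` fits one global regression across all
paired plot observations, jointly over environments: SCB then has its
own plot-level records and can be carried through the same stage-one
machinery as any other trait. (Fitting per environment would also be
defensible; the global fit was chosen because SCB is treated as a
trait with its own heritability, which requires plot-level residuals
on a common scale.) The residuals are mean-zero and exactly orthogonal
to SG by construction.

## Stage one: plot model, heritability, adjusted entry means

Per trait, plot values follow

$$y_{ijk} = \mu + g_i + l_j + (gl)_{ij} + r_{jk} + e_{ijk},$$

with clone $i$, environment $j$ (a year × location combination) and
replicate $k$ nested in environment. For variance-component estimation
all effects are random; `fit_plot_model()` obtains the five REML
components with `lme4::lmer`, which constrains them to be non-negative
(boundary REML). Correctness is pinned independently: the package
carries a direct dense-matrix evaluator of the restricted
log-likelihood, and the test suite verifies that the fitted optimum
meets or beats an exhaustive five-dimensional grid on small instances
to $10^{-6}$. A constant response is handled as an exact degenerate
fit (all components zero) rather than an optimizer failure. Designs
with a single environment are rejected with an identifiability error
naming the confounded pair of effects.

Heritability on an entry-mean basis is

$$h^2 = \frac{\sigma^2_g}{\sigma^2_g + \bar w / 2},$$

where $\bar w$ is the mean variance of a difference between two
adjusted entry means. The denominator convention differs between
texts; `estimate_heritability(variant = "plabstat")` switches to
$\sigma^2_g / (\sigma^2_g + \bar w)$. The default follows the standard
entry-mean form. On balanced complete data, effects shared by two
clones (environment, replicate) cancel in differences, so
$\bar w = 2(\sigma^2_{gl}/J + \sigma^2_e/(JK))$ with $J$ environments
and $K$ replicates — a closed form the tests verify against the
matrix computation.

For adjusted entry means, genotype is treated as fixed and the
non-genetic components are plugged in as known:
`adjusted_entry_means()` solves Henderson's mixed-model equations on
sparse incidence matrices, giving the GLS estimates
$M_i = \hat\mu + \hat g_i$ (cell-means coding), their standard errors
from the exact fixed-effect covariance $(X'V^{-1}X)^{-1}$, and
$\bar w$ as the average of $\mathrm{Var}(M_i - M_{i'})$ over all clone
pairs. On balanced data these GLS means coincide with arithmetic clone
means (the tests assert this identity); with unbalanced data they are
shrunk toward the environment structure, and the implementation is
checked against a brute-force dense GLS oracle. Clones without
observations are flagged inestimable and excluded from stage two, never
silently dropped. Missing plot values are simply absent from the
analysis; no imputation is attempted. If the residual component is
estimated at exactly zero, a tiny floor (relative to the trait
variance) keeps the equations well posed.

## Relatedness: kinship and structure

The kinship matrix uses a Loiselle-type moment estimator on fragment
presence frequencies: with $\bar p_m$ the panel frequency of fragment
$m$,

$$K_{ij} = \frac{\sum_m (x_{im}-\bar p_m)(x_{jm}-\bar p_m)}
               {\sum_m \bar p_m (1-\bar p_m)},$$

summing over fragments non-missing in both clones (pairwise deletion).
Negative off-diagonals are truncated at zero — unrelated rather than
"negatively related", the convention of the PK-method literature — and
the diagonal is set to 1, the maximal self-similarity, because dominant
scoring hides inbreeding; both choices are arguments of
`kinship_matrix()`, and a simple shared-fragment similarity estimator
is available as a strategy option. Because REML requires a valid
covariance, $2K$ is bent to positive semi-definiteness by the smallest
ridge $\varepsilon \in \{0\} \cup \{10^{-8}\cdot 2^t\}$; the object
records whether bending occurred.

Population structure uses classical principal coordinates of the
fragment matrix (equivalently, principal components of the
mean-imputed, column-centered 0/1 matrix; the scores reproduce the
pairwise Euclidean distances of that matrix, which the tests check to
$10^{-8}$). The number of retained axes $q$ is the smallest integer
whose cumulative explained variance reaches the target (default 25%).
Kinship and PCoA deliberately differ in missing-data handling
(pairwise deletion vs mean imputation): kinship terms are per-pair
sums, while PCoA needs one complete matrix.

## Stage two: the PK (Q+K) single-marker model

Each fragment $p$ is tested in

$$M_i = \mu + \sum_u P_{iu} v_u + a_p x_{ip} + \tilde g_i + e_i,
\qquad \mathrm{Var}(\tilde g) = 2K\sigma^2_{\tilde g},\quad
\mathrm{Var}(e) = R\,\sigma^2_r,$$

where $R$ is diagonal with the squared standard errors of the adjusted
entry means — the stage-one uncertainty propagated into stage two.
`fit_pk()` whitens by $R^{-1/2}$, eigendecomposes
$R^{-1/2}\,2K\,R^{-1/2}$ once, and profiles the restricted likelihood
over the variance ratio $\lambda = \sigma^2_{\tilde g}/\sigma^2_r$.
Numerical choices: the profile can be multimodal, so a coarse
log-spaced scan (41 points over $10^{\pm 8}$) brackets the optimum
before local refinement to $10^{-9}$; the boundary
$\sigma^2_{\tilde g} = 0$ is evaluated explicitly and wins ties; the
reported log-likelihood includes the whitening Jacobian so it is
directly comparable to a dense-matrix fit (the tests require agreement
with a generic two-parameter optimizer on dense $V$ to $10^{-6}$).
The fragment effect is the presence-vs-absence contrast; a Wald $t$
statistic on $n - \mathrm{rank}(X)$ degrees of freedom gives the
p-value. With $K = 0$, $R = I$ and no structure axes this reduces
exactly to OLS, and the marker test reproduces the equal-variance
two-sample t-test to $10^{-10}$ — an acceptance-level identity.

Effects are also reported in the deviation-from-population-mean
parameterization (`effect_popdev`, the presence contrast scaled by one
minus the carrier frequency), since published tables are sometimes in
that scale; the two agree in sign.

`scan_markers()` re-estimates both variance components for every
fragment (full per-marker REML; at a few hundred candidate fragments
this costs seconds). An EMMAX-style `reuse_vc = TRUE` mode fixes the
ratio at the null-model estimate. Clones missing a fragment's call are
excluded for that test only, with kinship, structure and weights
subset accordingly. Fragments with fewer than `min_count` (default 5)
carriers or non-carriers are skipped with a logged reason. No
multiplicity correction is applied to the reported p-values — raw
0.01/0.001 thresholds are the reporting convention in this literature —
but a Benjamini–Hochberg column is emitted alongside and never gates
output.

## Forward selection and explained genetic variance

`forward_select()` grows a multi-marker model: at each step every
remaining testable fragment is fitted as the last fixed term given the
already-selected fragments, the smallest Wald p enters if it beats
`p_enter` (default 0.001), ties break by larger absolute effect and
then fragment name, and no backward elimination is performed. Variance
components are re-estimated at every fit (the cheaper
fixed-at-null-fit alternative was rejected as the default because the
selected fixed effects change the residual structure). Fragments with
missing calls are mean-imputed inside the multi-marker design so all
steps share one clone set; collinear candidates are skipped with a
logged reason.

Explained genetic variance is defined as the percent reduction of the
REML genetic variance component between the null model and the model
containing all selected fragments, floored at zero. An alternative
definition (R² of the selected markers on the entry means, scaled by
h²) is available behind a flag. **Identifiability caveat:** the split
between $2K\sigma^2_{\tilde g}$ and $R\sigma^2_r$ is driven by the
off-diagonal structure of $K$ (and variation in $R$). In a panmictic
panel the estimated $K$ is close to the identity and $R$ close to
constant, the two components are nearly collinear, and the REML split
— hence the explained-variance figure — is noisy and boundary-prone,
even though the fixed-effect tests remain calibrated (the total
covariance is what matters for them). The accounting is meaningful for
panels with real relatedness structure, such as breeding germplasm
related by descent; the validation suite therefore exercises it on
simulated family-structured panels, and additionally with a planted
fragment chosen to carry within-family variance so that the
explained-variance bookkeeping is not confounded with the structure
covariates.

## The synthetic-data generator

`sim_config()`/`simulate_markers()`/`simulate_trial()` emulate the
target study design; the defaults are the study conditions the
package is validated under: 205 clones, 362 dominant fragments, 6
environments × 2 replicates, variance components
$(\sigma^2_g, \sigma^2_l, \sigma^2_{gl}, \sigma^2_r, \sigma^2_e) =
(100, 50, 30, 10, 40)$ on the index scale (entry-mean $h^2 \approx
0.92$, in the range reported for bruising and specific gravity in real
panels), trait intercept 25 index points, and a 5% missing-call rate.
Choices the design leaves open were fixed once as follows:

* **Markers.** Tetraploid dosage is not simulated; fragments are
  generated directly as dominant presence/absence, matching the 0/1
  scoring actually used. Subpopulation structure follows a
  Balding–Nichols model: ancestral frequencies uniform on
  $(0.1, 0.9)$, per-subpopulation frequencies Beta-distributed around
  them with divergence `fst` (default 0.15), per-clone admixture from
  a symmetric Dirichlet. With `n_subpops = 1` the panel is panmictic.
  Many subpopulations with near-pure membership emulate a
  family-structured panel.
* **Generating kinship.** The truth object records the same moment
  form the estimator uses, evaluated on the generating presence
  probabilities (untruncated off-diagonals, unit diagonal) — the
  noiseless analogue of what the estimator targets.
* **Genetic values.** $g_i$ is the sum of planted QTL contributions
  (effect × fragment code, in trait units, missing calls imputed at
  the fragment frequency) and a polygenic term drawn from
  $\mathcal N(0,\, 2K_\mathrm{true}\sigma^2_u)$ with $\sigma^2_u$
  scaled so the polygenic marginal variance equals
  `polygenic_h2_share` × $\sigma^2_g$. QTL effects are kept literal so
  power and recovery can be stated in residual-SD units; with QTL
  present the total genetic variance is the polygenic share plus the
  realized QTL variance (and equals $\sigma^2_g$ exactly when
  `qtl_spec` is empty).
* **G×E.** Drawn iid normal, no crossover structure — the plot model
  treats $(gl)_{ij}$ as unstructured.
* **Bruising counts.** `simulate_bruising_counts()` inverts the index:
  for a latent index $b$, all probability mass goes to the two
  categories whose weights bracket $b/100$, split so the expected
  recomputed index equals $b$ exactly; counts are multinomial. Tubers
  per plot defaults to 100 (roughly the 8–12 kg of tubers a bruising
  test exposes); within-plot tuber-count variation is not modeled, as
  no reference protocol specifies it.
* **Randomness.** Every stochastic operation takes an explicit seed
  and restores the caller's RNG state; identical configs give
  byte-identical outputs.

What the generator does **not** emulate: tuber physiology and
storage/impact calibration, crossover G×E, linkage disequilibrium
within loci (fragments are drawn independently given ancestry, so LD
exists only through population structure), dosage, genotyping error,
and non-normal trait distributions. Passing tests therefore show that
the estimators are correct and calibrated under the stated model, not
that real bruising data meet that model.

## Validation problem sizes

The statistical acceptance suite runs at the following sizes, chosen
to make each property identifiable while keeping the whole suite at
desk scale: type-I calibration on 50 null trials × 200 fragments at
205 clones (p < 0.001 rate within the central 99% binomial band);
variance recovery and heritability coverage on 50 trials; power on 50
trials with a +1.5 residual-SD effect at a ~30%-frequency fragment
(≥ 80% detection at p < 0.001 with correct sign); forward-selection
null behaviour on 50 trials with a 10-fragment candidate panel (the
familywise null-entry probability at `p_enter` 0.001 is then ~1%,
within the 5% the check allows — at a 362-fragment panel a raw
per-test threshold of 0.001 implies a ~30% familywise null-entry rate,
a property of raw-threshold forward selection, not a defect);
explained-variance recovery on 50 family-structured trials (20
families, `fst` 0.5, kinship from 500 fragments, candidate scan over
100). Grid oracles use 8–15 clone instances. The Mantel check of the
kinship estimator against the generating kinship uses 2 subpopulations
at `fst` 0.3 — the criterion explicitly concerns a structured panel,
and at the generator's default divergence of 0.15 the signal spread is
comparable to the estimator's sampling noise at a few hundred
fragments, so the correlation is capped by noise rather than by
estimator quality.

## Known limitations

* Stage two conditions on the estimated kinship; noise in $K$
  attenuates $\sigma^2_{\tilde g}$ (a classic errors-in-variables
  effect), which is why explained-variance recovery is validated with
  a several-hundred-fragment kinship panel.
* Wald $t$ with residual degrees of freedom is the default
  single-marker test; no Kenward–Roger-type correction is attempted. A
  likelihood-ratio alternative (`scan_markers(test = "lr")`, ML
  likelihoods with and without the marker on one chi-square degree of
  freedom) is provided behind a flag.
* The pipeline assumes one record per clone × environment × replicate
  × trait; duplicated keys are a schema error, not averaged.
* Entry means for clones observed in a single environment are
  estimable but strongly shrunk toward that environment's level; their
  standard errors reflect this.
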