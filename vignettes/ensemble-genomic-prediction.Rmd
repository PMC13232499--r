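---
title: "Ensemble genomic prediction with diversity decomposition: models and methods"
author: "gpensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble genomic prediction with diversity decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gpensemble)
```

# Scope

`gpensemble` studies equal-weight ensembles of six genomic prediction models
on nested association mapping (NAM) recombinant inbred line (RIL)
populations, using the Diversity Prediction Theorem to attribute the
ensemble's error reduction to the diversity of its members' predictions.
Because the real teosinte-NAM and maize-NAM downloads are external data, the
package carries a first-class synthetic generator whose presets emulate the
structure of those two designs; every stage of the pipeline is exercised and
tested offline on that generator.

# The synthetic NAM worlds

`simulate_ril_population()` develops each line independently at the gamete
level.  Crossovers follow a Poisson process at 1 event per 100 cM with no
interference (the Haldane model) — the simplest defensible meiosis model, and
the one whose map function we can verify in closed form.  The
`backcross_then_self` scheme (one backcross to the recurrent parent, then 4
selfing generations by single-seed descent) gives the exact single-locus
expectations tested in the suite: donor-allele frequency 1/4 and residual
heterozygosity $(1/2)^4 = 0.0625$ at the F5-equivalent stage.

`simulate_phenotypes()` builds the genetic value as a sum of additive dosage
effects plus pairwise dosage-product interactions.  Two numerical choices
matter:

* the interaction component is orthogonalised against the additive component
  before scaling (dosage products are correlated with dosages, so without
  this the two variance targets cannot be met jointly);
* the additive component anchors the phenotypic variance
  ($V_P = V_A / h^2_a$ when $h^2_a > 0$), the interaction component and the
  residual are rescaled around it, so realized variance fractions match the
  targets in expectation.  With no genetic signal at all the residual
  defaults to unit variance.

The two presets state the worlds once.  `"teonam"`: 5 BC1-derived selfed
populations on W22, 450-620 RILs, ~350 SNPs before pruning, two environments
with raw records, DTA-like trait with targets $h^2_a = 0.45$,
$h^2_e = 0.15$ and ASI-like with $(0.40, 0.12)$ — the ASI targets are lower
because that trait's genetic components are the smaller ones in both real
datasets.  `"maizenam"`: 25 F5 populations on B73, 125-200 RILs, ~220 SNPs,
four environments reduced to BLUEs, mostly additive architectures
$(0.55, 0.11)$ and $(0.40, 0.09)$.  Population counts and SNP/RIL ranges
follow the published dataset tables; per-population heritabilities are not
published for the teosinte NAM, so the presets approximate the qualitative
contrast (higher diversity, larger epistatic share) only.  The generator
does not model selection during line development, mutation, or segregation
distortion; a green test on this world establishes correctness of the
pipeline's computations, not realism of any particular maize dataset.

# Preprocessing

Missing genotypes are imputed from the nearest non-missing flanking marker
in cM on the same chromosome (left flank on exact ties; chromosome ends copy
the single available flank).  RILs with a whole-missing chromosome or no
phenotype are removed with a logged reason.  LD pruning is
indep-pairwise-style: within a 30-kb window stepped by 5 SNPs, one marker of
every pair with squared dosage correlation at or above 0.8 is removed — the
lower-MAF marker, the later map position on ties.  A final audit pass
guarantees no surviving pair within 30 kb violates the threshold, which is
exactly the property the test suite re-checks by brute force.  Monomorphic
markers have undefined $r^2$; their pairs are skipped and the markers
flagged rather than dropped silently.

Multi-environment data are concatenated: one record per (RIL, environment)
sharing the RIL's genotype row, with the environment entering the models as
one-hot-minus-reference feature columns rather than as a pre-adjustment.
BLUPs are fitted per population by a two-stage scheme (environment-mean
adjustment, then line means shrunken by the line-mean repeatability $H^2$
from the one-way ANOVA mean squares), and BLUEs are the exact inverse of
that shrinkage, $\mathrm{BLUE}_i = \mathrm{BLUP}_i / H^2$ on the centred
scale — the one-parameter reading of "unshrinking by heritability".

# Variance partition

The additive genomic relationship matrix is $G_A = WW'/n$ with $W$ the
column-mean-centred dosage matrix and $n$ the number of individuals.  This
$/n$ scaling is deliberate and followed literally even though it differs
from the common $2\sum p_j q_j$ marker-based scaling; consequently the raw
$\sigma^2$ components are on the $G$ scale, and parameter-recovery tests
simulate from the model ($a \sim N(0, \sigma^2_A G_A)$) rather than by
fixing empirical component variances.  The epistatic matrix is the
trace-normalised Hadamard square, $G_{AA} = (G_A \odot G_A) /
(\mathrm{tr}(G_A \odot G_A)/n)$, so $\mathrm{tr}(G_{AA}) = n$ exactly.

The extended GBLUP $y = X\beta + a + t + \varepsilon$ with
$a \sim N(0, G_A\sigma^2_A)$, $t \sim N(0, G_{AA}\sigma^2_E)$ is fitted by
REML: average-information updates with step-halving, an EM fallback when the
AI step fails, active-set handling of components pinned at the $10^{-8}$
floor (nonnegativity is enforced; ASReml-style negative components are not
allowed), and convergence at $|\Delta \log L| < 10^{-6}$ or a score norm
below $10^{-4}$.  Setting `GAA = NULL` drops the epistatic term and reduces
the fit to standard GBLUP, which the tests check against an independent
eigendecomposition closed form.  Identifiability caveat: with unstructured
(linkage-equilibrium) genotypes $G_A$ approaches a scaled identity and the
three components are confounded; on realistic RIL panels with LD and kinship
structure the partition is well determined, which is why the tests build
their panels through the gamete simulator.

# The six prediction models

All models share a fit/predict contract (genotype matrix plus optional
fixed-effect columns; predictions aligned to the test rows) and are
deterministic given data, hyperparameters and a seed.

* **rrBLUP** — Gibbs sampler, common normal prior over all marker effects,
  scaled-inverse-$\chi^2$ hyperpriors; flat priors on fixed effects.  With
  variances fixed, the posterior mean is the closed-form ridge solution
  $(X'X + \lambda I)^{-1}X'y$, the suite's oracle.
* **BayesB** — per-marker point mass at zero (prior exclusion probability
  $\pi = 0.5$ under a Beta(5,5)-weighted hyperprior) with a df = 5 scaled-t
  slab.  "Default values" of the original software are not published, so
  these standard Bayesian-alphabet defaults are config-visible and
  overridable.
* **RKHS** — Gaussian kernel $K_{ij} = \exp(-d^2_{ij}/(h \cdot
  \overline{d^2}))$ on squared Euclidean genotype distances (off-diagonal
  mean, bandwidth $h = 1$, single kernel), sampled on the kernel's scaled
  eigenbasis with the same ridge-type sampler.
* **RF** — bagged CART regression trees grown to purity, $\lfloor p/3
  \rfloor$ candidate features per split, minimum split size 5, 1000 trees;
  impurity decreases are recorded per node for importance.
* **SVR** — $\varepsilon$-insensitive RBF regression at library-typical
  defaults ($C = 1$, $\varepsilon = 0.1$, $\gamma = 1/(p \cdot
  \mathrm{var}(X))$).  The dual is solved by cyclic coordinate descent with
  the offset fixed at the training mean instead of a free intercept with an
  equality constraint; the defining $\varepsilon$-tube behaviour (a response
  inside the tube yields an exactly flat predictor) is preserved and tested.
* **MLP** — one hidden ReLU layer; dataset presets (50 units / dropout 0 /
  200 epochs / AdamW for the teosinte-like world; 10 / 0.1 / 2500 / RMSprop
  for the maize-like world), learning rate 0.005, minibatches of 32.  Inputs
  are standardised on training statistics only; the response is centred
  internally (and restored at prediction) because with a raw mean of ~70
  days the bias could not reach the data range within the stated epochs.

The published chain lengths (12,000 iterations, 2,000 burn-in) are the
`"full"` hyperparameter profile; the `"test"` profile (2,000/500, 200 trees,
shortened MLP epochs) exists purely for desk-scale runs and is what the test
suite and the analysis drivers use.  None of rrBLUP/BayesB/RKHS/RF/SVR/MLP
had usable implementations in the build environment, so all six are
implemented in the package (compiled samplers/forest/optimisers) with
independent oracles in the tests.

# Marker effects

Linear models report posterior-mean allele substitution effects; the forest
reports summed impurity decreases; RKHS/SVR/MLP are explained by
interventional Shapley values: absent markers take values from a background
set, contributions accumulate along sampled marker orderings, and the
telescoping construction makes the efficiency identity
$\sum_j \phi_j = f(x) - \overline{f(\mathrm{background})}$ hold exactly for
the backgrounds used.  The per-marker effect is the mean absolute Shapley
value over the explanation set (no standard exists for aggregating
per-individual attributions into one marker effect; the mean of absolute
values keeps sign-free comparability).  The explanation set defaults to a seeded subsample of the
training split with a seeded background of the same origin.

Pairwise marker-by-marker interactions from the forest use the Shapley
interaction index estimated by its exact sampling distribution: for a pair
$(i, j)$ the size of the conditioning set is uniform on $0..p-2$ (this
uniformity is what the combinatorial weights collapse to), the set is drawn
uniformly at that size, and the sampled quantity is the second difference
$f(S{+}ij) - f(S{+}i) - f(S{+}j) + f(S)$.  An exact tree-traversal
interaction algorithm was considered and rejected: no SHAP library exists
for R in this environment and the sampling estimator is unbiased, symmetric
by construction, and testable against recovery/null cases.  The selected
set is the top 0.01% of pairs by absolute score
($\lceil 10^{-4} p(p-1)/2 \rceil$ pairs).

Per model and scenario, effects are normalised by their maximum absolute
value ("normalised" is otherwise undefined; z-scoring is available as an
option), the ensemble profile is the per-marker mean of the six normalised
profiles, and genome tracks bin markers into 10 empirical-CDF decile levels
(ties share the lower level, so a constant profile sits in level 1).
Absolute values are used for track intensity; the sign question for plotted
Shapley scores is left open deliberately.

# Ensemble and diversity decomposition

The ensemble prediction is the per-sample mean $\bar M$ of the six member
predictions.  For observed values $V$ the theorem states
$(\bar M - V)^2 = \sum_i (M_i - V)^2/N - \sum_i (M_i - \bar M)^2/N$:
ensemble (Many-Model) error = mean member error − prediction diversity.
Scenario-level term values are means over the scenario's test samples —
this choice makes term 1 equal the ensemble's MSE exactly, which the runner
asserts for every scenario.  Group summaries report mean, standard error
across scenarios (not test samples), and $CV = s/\bar x$ pooled over all
ratios, populations and replicates within a trait-by-dataset group.  A
single scenario leaves CV and SE flagged unavailable; a zero mean flags the
CV undefined.

# Evaluation design

Scenarios are (population × train/test ratio × replicate) units with the
published ratio set {0.8/0.2, 0.65/0.35, 0.5/0.5}; splits are sampled at the
RIL level so both environment records of a RIL stay on one side (leakage
through the shared genotype row is otherwise possible), one split per
scenario shared by all models.  Metrics are Pearson correlation (missing
for zero-variance degenerate cases, with counts reported) and MSE; groups
are summarised by medians, robust to the occasional extreme scenario.
Top-3 shares use competition ("1224") ranking so all models tied at rank 3
count.  A failed model excludes its scenario from ensemble/diversity
accounting but keeps the surviving members' own metrics.

Seeds derive from one global seed through a collision-checked string hash
(`derive_seed`), with distinct stage tags for splits, per-model fits and
Shapley draws, so any scenario is reproducible in isolation.

# Desk-scale choices

The full published grids (7,500 and 3,750 scenarios per trait) are a config
choice; the analysis drivers default to 5 replicates per (population,
ratio) and the acceptance checks use the stated test profile (2 populations
× 3 ratios × 10 replicates at ~150 RILs / ~200 markers).  The
high-vs-low-diversity comparison keeps each preset's own structure but
scales the teosinte-like population size down (and its replicate count)
for single-CPU runtime; this is a runtime scaling, not a re-statement of
the worlds.

# What the synthetic worlds do and do not reproduce

The mechanism of the diversity decomposition carries over to the synthetic
worlds: the high-diversity (teosinte-like) preset yields a larger *mean*
prediction-diversity term than the low-diversity (maize-like) preset, as in
the real datasets.  The *coefficient of variation* of that term across
scenarios does not reproduce the real contrast at desk scale: in the real
teosinte NAM the term's spread is driven by heterogeneity between five very
different donor populations, whereas the presets apply one shared QTL
architecture and noise level to statistically exchangeable populations, so
between-scenario spread is dominated by training-set size — which is
relatively larger in the smaller maize-like populations.  The package
reports this honestly (the ensemble's accuracy-gain direction holds on the
stated worlds; the CV-direction assertion fails) rather than adding
per-population heterogeneity after the fact; a generator extension with
donor-specific architectures is the natural follow-up.

# Known limitations

* The $/n$ scaling of $G_A$ makes raw variance components scale-dependent;
  proportions are comparable within an analysis but not across panels with
  very different marker counts.
* BLUE derivation assumes the one-parameter shrinkage inverse; a full
  mixed-model unshrinking with per-line reliabilities is out of scope.
* Shapley estimates are Monte Carlo; their variance is controlled by the
  permutation count, and the pairwise estimator's cost grows quadratically
  in markers, so genome-wide interaction scans should subsample markers or
  explanation sets.
* The simulator draws QTL effects i.i.d. normal at mapped markers; allele
  frequency spectra, dominance and GxE beyond additive environment shifts
  are not modelled.
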