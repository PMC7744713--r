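---
title: "Methods: condition-specific regularized FBA and multi-omic machine learning"
author: "cyanoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: condition-specific regularized FBA and multi-omic machine learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyanoflux)
```

# Overview

`cyanoflux` implements a hybrid pipeline for photoautotrophic bacteria such
as *Synechococcus*: per-condition transcriptomes are integrated into a
constraint-based metabolic model, condition-specific flux distributions are
computed by bilevel L2-regularized flux balance analysis (FBA) for paired
growth/energy objectives, and the resulting transcript, flux and combined
feature matrices are mined with PCA, silhouette-selected k-means, Pearson
correlation against growth rates, and LASSO regression. This vignette
documents the model, the numerical choices, and the reasoning behind the
design decisions that were genuinely open.

# Constraint-based model and condition specialization

A model is stoichiometry $S$ (metabolites $\times$ reactions), flux bounds
$l \le v \le u$ (mmol gDW$^{-1}$ h$^{-1}$), pathway (subsystem) labels, and
gene-protein-reaction (GPR) rules. Steady state imposes $S v = 0$. Exchange
reactions use the standard sign convention: negative flux is uptake,
positive is secretion. Files missing explicit bounds get the conventional
$\pm 1000$ defaults; unknown SBML annotations are ignored for forward
compatibility. Invariants (bound ordering, id uniqueness, GPR
well-formedness, gene coverage) are checked on every construction path and
violations always raise errors — a silently clamped bound would corrupt
every downstream flux.

Two inputs specialize the model per growth condition, in a fixed order:

1. **Expression integration.** Fold changes vs the control,
   $\theta_g = (x_g + \varepsilon)/(c_g + \varepsilon)$ with a pseudocount
   $\varepsilon$ defaulting to $10^{-8}\times$ the control median
   (machine-scale: it only guards zero denominators), are mapped to
   reaction activities through the GPR rules — `and` takes the minimum
   child (limiting subunit of a complex), `or` the maximum (best isozyme).
   Genes in the model but absent from the table are neutral
   ($\theta = 1$). Both bounds of reaction $r$ are then multiplied by
   $$f(\theta_r) = (1 + \gamma\,|\ln\theta_r|)^{\operatorname{sign}(\ln\theta_r)},$$
   with $\gamma = 1$ by default. This transform is symmetric in fold change
   ($f(\theta)f(1/\theta) = 1$), fixes $f(1) = 1$, is monotone in
   $\theta$, and reduces to a no-op at $\gamma = 0$; because the factor is
   positive, bound signs and ordering are always preserved and reversible
   reactions scale symmetrically. It is exposed as a pluggable function
   (`scale_fn` of `modulate_bounds()`) so an alternative
   expression-to-bound mapping can be substituted without touching the
   pipeline. We scale both bounds of irreversible reactions rather than
   only the thermodynamically feasible direction; for an irreversible
   reaction the lower bound is typically 0, where the two choices coincide.

2. **Explicit overrides.** Per-condition bound overrides (photon uptake
   from light intensity and culture optical density, medium composition,
   oxygen/CO$_2$ availability) are applied *after* integration, so
   measured constraints always take final precedence over inferred ones.

# Bilevel L2-regularized FBA

For each condition-specific model and each objective pair (primary:
biomass; secondary: ATP maintenance, photosystem I, or photosystem II) the
solve is lexicographic in three stages:

1. $Z_1 = \max v_{\text{primary}}$ (LP);
2. $Z_2 = \max v_{\text{secondary}}$ subject to
   $v_{\text{primary}} \ge f\,Z_1$ (LP), with the fraction-of-optimum
   $f = 1$ by default (biomass held at its optimum);
3. $v^\ast = \arg\min \lVert v\rVert_2^2$ subject to both objective
   constraints (strictly convex QP).

Staging guarantees the primary and secondary optima are respected exactly
while the L2 stage makes the returned flux vector *unique*: alternate
optima, such as two stoichiometrically identical parallel routes, collapse
to the balanced split (the package's parallel-pathway generator exists to
pin exactly this property). A single-QP alternative
($\max v_{\text{secondary}} - \lambda\lVert v\rVert^2$, $\lambda = 10^{-6}$)
is available for sensitivity checks; it trades exactness of $Z_2$ for a
one-shot solve.

**Numerics.** The QP engine is `quadprog`'s dual active-set method.
Equality constraints (mass balance plus any fluxes fixed by $l = u$) are
eliminated first by an orthonormal null-space reduction, leaving an
inequality-only QP in the network's degrees of freedom; this is better
conditioned than passing equalities to the active-set method and is immune
to the degenerate-vertex failures that otherwise occur when a condition
(e.g. darkness) pins the entire flux polytope to a single point.
Projection noise below $10^{-11}$ in the reduced constraint matrix is
truncated and rows are normalized. The LP stages are solved by exact
quadratic regularization: for a bounded polyhedron there is a finite
$M^\ast$ such that minimizing $\tfrac12\lVert v\rVert^2 - M c^\top v$ for
any $M \ge M^\ast$ yields the minimum-norm point of the LP optimal face
with $c^\top v$ exactly the LP optimum; $M$ is escalated tenfold until the
objective value stabilizes (tolerance $10^{-9}$), which certifies
$M \ge M^\ast$. Defaults: feasibility tolerance $10^{-9}$, optimality
tolerance and secondary slack $\varepsilon_2 = 10^{-6}$. Every returned
distribution is checked for $\lVert S v\rVert_\infty \le 10^{-9}$, bound
satisfaction, and $v_{\text{primary}} \ge f Z_1 - 10^{-6}$. Fluxes below
$10^{-9}$ in magnitude are snapped to exact zero in reported matrices; the
raw vector is kept. Infeasible conditions abort a batch with the condition
named — dark or stressed conditions are feasible-with-zero-flux, not
infeasible, so silent zero-filling would mask real errors.

# Feature assembly and normalization

Three feature sets are assembled per objective pair: transcripts only,
fluxes only, and their concatenation. Transcript features are analyzed on
the $\log(x+1)$ scale (expression is simulated, and usually measured, on a
multiplicative scale). Combined matrices concatenate raw values — each
downstream method controls its own scaling. For display-style comparisons
across conditions, each reaction's flux column can be divided by its
maximum *absolute* value across conditions (`normalize_by_reaction_max`),
mapping into $[-1, 1]$; using the maximum magnitude rather than the
maximum signed flux keeps reversible reactions bounded and coincides with
dividing by the control's flux whenever the control carries the maximum.
Standardization (z-scoring, dropping constant columns with a report) is
applied inside each analysis that needs it.

# PCA, clustering, growth association

**PCA** is computed by SVD of the centered (and by default unit-scaled)
matrix; with transcripts and fluxes on incommensurate scales, correlation
PCA is the only defensible default for mixed matrices, so `scale = TRUE`
unless the caller overrides it. Eigenvalues are
$\sigma_k^2/(n-1)$; `cos2`$(i,k)$ — the share of condition $i$'s squared
distance to the centroid captured by component $k$ — rows sum to 1;
feature contributions ($100 \times$ squared unit loading) sum to 100 per
component. Component signs are canonicalized by forcing each component's
largest-magnitude loading positive, since SVD sign is arbitrary.
Pathway-level aggregation sums each feature's contributions over a
component set (default $\{1,2\}$, as in the score plots) and then sums or
averages within subsystem/COG groups; means are sensitive to
single-feature pathways, so group sizes are reported alongside.

**Clustering** uses `stats::kmeans` (best of 50 random starts by
within-cluster sum of squares, fixed seed) on standardized features;
$k$ is selected by maximizing the mean silhouette width
($(b-a)/\max(a,b)$, Euclidean; singleton clusters score 0), with ties
broken toward smaller $k$ for parsimony. Labels are canonicalized by
first-member order so outputs are diffable. A PCA-reduced mode
(`pca_scores_matrix`) clusters on leading score columns to suppress noise
carried by minor components.

**Growth association** restricts to conditions with measured rates (never
imputes). Pearson correlations carry Fisher-z 95% intervals,
$\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$, and require
$n \ge 4$; records sort by $|r|$ with ties broken by feature id so the
order is a permutation-stable total order. Subsystem aggregation offers
mean $|r|$ and counts in half-open bins $[a, b[$ with default edges
$(-0.3, -0.1, 0.1, 0.3, 0.5, 0.7)$. **LASSO** uses `glmnet` with internal
standardization and centered response; the penalty grid is 100 log-spaced
values spanning 4 decades below $\lambda_{\max}$ (the smallest penalty
shrinking all coefficients to zero, computed with $10^{-6}$ relative
headroom so the grid top sits at or above the first entry point).
Cross-validation is leave-one-out by default — with 12-24 conditions,
k-fold splits waste data and add fold-assignment variance — and both the
minimum-CV and one-standard-error rules are implemented (min-CV default).
Coefficients are reported on the original and standardized scales;
"nonzero" means $|\beta| > 10^{-10}$ after an exact refit at the selected
penalty. The count of nonzero coefficients along the grid is recorded
(`path_nonzero`) together with a monotonicity flag: monotone shrinkage
with increasing penalty holds reliably in the low-dimensional regime but
is **not** a theorem for the LASSO path — with $p > n$ variables can
leave and re-enter — so the flag is informative, not an assertion the
fitter enforces.

# What the synthetic study emulates — and what it does not

`make_synthetic_study()` generates the study-shaped conditions the
pipeline is tested under: a 9-reaction photoautotroph toy (photon, CO$_2$
and O$_2$ exchanges; photosystem-II- and photosystem-I-like reactions
coupled through a plastoquinone-like carrier; a Mehler-like NADPH valve; a
Calvin-cycle-like fixation lump; ATP maintenance; biomass), 24 conditions
with log-normal expression in six planted clusters (between-cluster shift
6 on the log scale, within-cluster sd 1), per-condition photon-uptake
overrides including one dark (photon pinned to zero) and one high-light
condition plus occasional carbon limitation, and growth rates from a
sparse linear model over the standardized log-transcript features (3
nonzero coefficients, signal-to-noise ratio 10) reported for 12 of the 24
conditions. Every generator is a pure function of its arguments and seed,
and ground truth (cluster labels, coefficient vector, noise sd) is stored
next to the data, so tests compare pipeline output to planted truth rather
than to hard-coded numbers.

Defaults were chosen once to mirror the study shape (24 conditions, a
control plus perturbations, three objective pairs, 12 measured growth
rates) with effect sizes a field scientist would call clearly structured
data: cluster shift 6 makes clusters unambiguous, SNR 10 makes the
regression signal strong but noisy. Sizes were chosen so the complete
pipeline runs in seconds on one core.

Limits worth keeping in mind: expression noise is log-normal, not the
negative-binomial count noise of real RNA-seq; the toy network has ~2
degrees of freedom, so flux matrices are effectively rank-2 and flux PCA
explains 100% of variance in two components (real genome-scale models
spread variance much further); the planted clusters make transcripts
within a cluster strongly collinear, so LASSO may select correlated
proxies instead of the planted genes — support recovery on this fixture
is a property of the design, not of the fitter (the i.i.d.-design
recovery rate is pinned separately at $\ge 90/100$ seeds). Passing tests
demonstrate correctness of the machinery, not biological fidelity of the
toy.

# Pipeline and reproducibility

`run_pipeline()` executes the whole workflow from a config (paths, control
condition — named explicitly, never inferred —, objective pairs,
integration/solver settings, feature modes, analyses, seed) and writes a
CSV bundle plus a manifest (config echo, seeds, package version, per-stage
status). The manifest contains no timestamps, and every random step is
seeded, so a bundle re-runs bit-identically; a failing stage marks the
manifest `failed` with the stage name and retains partial outputs. The
numbered drivers under `analysis/` run the same stages step by step on the
synthetic study, and `scripts/acceptance.R` recomputes the headline
quantities from scratch for a given seed.

```{r example, eval = FALSE}
study <- make_synthetic_study(seed = 1)
dir <- tempfile(); write_study(study, dir)
cfg <- pipeline_config(
  model_path = file.path(dir, "model.json"),
  expression_path = file.path(dir, "expression.csv"),
  conditions_path = file.path(dir, "conditions.csv"),
  growth_path = file.path(dir, "growth.csv"),
  out_dir = file.path(dir, "bundle"),
  control_id = "cond01", seed = 1)
manifest <- run_pipeline(cfg)
manifest$status
```

# Known limitations

Dense LP/QP solves scale comfortably to a few hundred reactions; a
genome-scale model with thousands of reactions would want a sparse LP/QP
backend behind the same three-stage interface. Flux variability analysis,
MOMA-style perturbation prediction and dynamic/diurnal FBA are out of
scope. The SBML support covers the Level 3 FBC v2 subset the pipeline
round-trips (species, reactions, bound parameters, gene products,
objectives, subsystem groups), not the full standard.
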