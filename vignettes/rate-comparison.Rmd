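---
title: "Comparing Brownian evolutionary rates among traits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing Brownian evolutionary rates among traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitrates)
```

## The model and its assumptions

`traitrates` asks whether p continuous traits have diversified at different
rates across a rooted phylogeny with branch lengths. The traits are modelled
as a p-variate Brownian motion: along every branch, trait change is normal
with mean zero and covariance proportional to branch length, so the n×p tip
matrix X is matrix-normal with mean `1 μ'`, row covariance C (the
phylogenetic covariance matrix of shared root-to-tip path lengths) and
column covariance R (the evolutionary rate matrix),

$$\log L = -\tfrac12\!\left[np\log(2\pi) + p\log|C| + n\log|R|
  + \mathrm{tr}\!\left(R^{-1} D' C^{-1} D\right)\right],
  \qquad D = X - \mathbf{1}\hat\mu'.$$

The diagonal of R holds the per-trait Brownian rates σ²ᵢ — variance accrued
per unit branch length — and the off-diagonals are evolutionary covariances
between traits. Assumptions worth stating plainly: gradual, direction-free
(no-trend) evolution; a single rate regime over the whole tree (no shifts
between clades); correct branch lengths up to a global scale (the LRT below
is invariant to rescaling all branch lengths, so the time units do not
matter, but relative branch lengths do); and traits measured without error
at one value per species. Trait values are analysed on the log10 scale so
that rates describe proportional, unit-free change; the likelihood core
itself is transformation-agnostic and the log10 transform is applied by the
assembly layer (`load_traits`/`assemble_dataset`) when reading files.

Two nested models are fitted. The **observed** model leaves R free and has
a closed-form ML solution: the GLS mean
$\hat\mu = (1'C^{-1}1)^{-1}1'C^{-1}X$ followed by $\hat R = D'C^{-1}D/n$
(ML divisor n). The **common-rate** model forces every diagonal entry of R
to one σ². Because $\hat\mu$ does not depend on R, profiling the mean out
is exact for both models. The models are compared with
$LRT = 2(\log L_{obs} - \log L_{common}) \sim \chi^2_{p-1}$ and with
AIC = −2 logL + 2k, counting k = 2p parameters for the observed model
(p rates + p means) and k = p + 1 for the common model (one rate + p
means). Evolutionary covariances appear identically in both models and are
not counted; this convention makes the parameter-count difference equal the
LRT degrees of freedom p − 1, and it reproduces, to printed rounding, every
published AIC↔logL pair in the reference summaries shipped as
`published_fits()` (checked by the test suite and the acceptance script).

## The common-model parameterisation

How exactly the constrained model treats the trait covariances was a
genuinely open design point. Two parameterisations are implemented:

* `"joint"` (default): R_c has equal diagonal σ² and *free* off-diagonal
  covariances, all estimated jointly — the full constrained maximum
  likelihood.
* `"fixed_correlations"`: R_c(σ²) = σ²P with P pinned at the observed-model
  correlation matrix, and only σ² optimised (a 1-D profile).

The default is `"joint"`, for two reasons. First, only the full constrained
maximum gives a proper likelihood-ratio test: the 1-D profile understates
logL_common, inflates the LRT, and in our calibration simulations (run by
the test suite and by `scripts/acceptance.R`) pushes the type-I error at
n = 15, p = 4 to ~0.14, versus ~0.08–0.10 for the joint fit. Second,
published common-model covariances in this literature are not proportional
to the observed correlations, which is the signature of a joint fit. The
fixed-correlation profile is retained because it is cheap, deterministic,
easy to audit against a grid search, and supplies the starting point for
the joint optimiser.

## Numerical strategy

C is Cholesky-factorised once per dataset; all quadratic forms and
log-determinants flow from that factor (no explicit inverses). Results
agree with naive dense inversion — and with a brute-force np×np
Kronecker-covariance normal density — to better than 1e-8 (tested). The 1-D
profile for σ² uses deterministic bounded scalar maximisation on the log
scale (relative tolerance 1e-10, bracket 1e-4–1e4 × the observed rate
range); the test suite checks it against a 1000-point log-spaced grid with
refinement (agreement within 0.1%) and against the analytic optimum
tr(P⁻¹D'C⁻¹D)/(np). The joint fit runs BFGS on (log σ², covariances) with
the analytic gradient ∂logL/∂R = −(nR⁻¹ − R⁻¹SR⁻¹)/2, started at the 1-D
profile optimum; non-positive-definite iterates are rejected by penalty.
There are no random starts anywhere — fits are deterministic.

Degenerate inputs are errors, never silent repairs: two tips at zero
patristic distance make C singular and are reported by name at fit time
(parsing deliberately accepts zero-length branches); duplicated or
collinear trait columns raise a collinearity error; non-positive values
under a log10 transform abort; a non-positive-definite R is refused rather
than jittered, since any jitter would contaminate the LRT arithmetic.
Pruning a tree keeps the root-ward stem as a root edge so that the pruned
covariance equals the corresponding submatrix of the full covariance — an
invariant the test suite enforces on random trees and subsets.

## Tunable parameters

* `common_model` — `"joint"` (default) or `"fixed_correlations"`; see above.
* `alpha` (post hoc lettering) — significance level, default 0.05.
* `adjust` — multiple-testing correction for post hoc pairwise p-values,
  default `"none"` (raw p-values, matching standard practice in this
  literature); any `p.adjust` method can be selected.
* `log10` (assembly) — default on; rates are then in squared log10 units
  per unit branch length. Mixed measurement units across columns corrupt
  log-scale rates, so an optional per-column unit declaration aborts on
  mixtures; the package never converts units.
* `strict` (newick) — whether a missing trailing semicolon is an error
  (default: repaired with a warning). Branch lengths are mandatory on all
  edges; polytomies and quoted labels are accepted; a root edge on input is
  ignored.

Post hoc grouping letters are built by covering the non-significance graph
(edge when p > α) with cliques found greedily in trait input order — the
field's tables do not specify a lettering algorithm, so the package uses
the simplest construction whose guarantee is easy to state: two traits
share a letter if and only if they lie in a common clique, so a shared
letter always certifies a non-significant pair. Ties are broken by input
order.

## What the simulator emulates — and what it does not

`simulate_tree` draws pure-birth (Yule) trees conditioned on the tip count
and rescales them to unit height, so simulated rates are in
per-tree-depth units and comparable across replicates; `simulate_traits`
draws X = 1μ' + L_C Z U_R exactly from the model above. Both are fully
determined by an integer seed and restore the caller's RNG state. Two
presets emulate the structure of the motivating datasets: `"drosophila"`
(19 taxa, 4 traits — fertile and non-fertile total sperm length, wing
length, seminal receptacle length — true rates 0.99, 0.29, 0.03, 1.09) and
`"lepidoptera"` (12 taxa, 3 traits, true rates 0.053, 0.014, 0.032). Preset
values are written as linear micrometre lengths so the log10 ingestion path
is exercised end to end; the generating root states are plausible organ
sizes. The preset evolutionary correlations are *synthetic*: they are the
correlations implied by published observed covariance summaries and should
be read as realistic magnitudes, not as measurements. An option emulates
incomplete trait coverage (blanking the last trait for four species) to
exercise complete-case pruning.

What passing simulation tests does and does not show: the generator draws
from exactly the model the estimator assumes, so these tests certify the
estimation and testing machinery, not the model's adequacy for real data.
Real comparative data add measurement error, within-species variation,
possible rate shifts across clades, non-Brownian dynamics
(Ornstein–Uhlenbeck pull, early bursts), and tree uncertainty — none of
which the simulator emulates, and none of which the package models.

## Problem sizes and known limitations

The shipped tests and the acceptance script use the scales of the
motivating analyses: n = 11–19 species, p = 2–4 traits, 200-replicate
recovery runs and 1000-replicate calibration runs (n = 15). At these sizes
every fit is closed-form or a few dozen gradient steps, and the full suite
runs in a few minutes.

Known limitations, deliberately accepted:

* **ML bias.** With divisor n, E[σ̂²] = (n−1)/n σ², and the χ² skew places
  the *median* estimate a further ~(2/3)/(n−1) below the truth — about
  −9% at n = 19 and −14% at n = 12. Rate *ratios* are nearly unaffected;
  recovery tests compare against the finite-sample target after the
  (n−1)/n correction.
* **Small-sample LRT calibration.** The χ²(p−1) reference is mildly
  anticonservative for covariance-structure tests at small n: in the
  calibration runs at n = 15 the empirical type-I error at α = 0.05 is
  ~0.07 for p = 2 and ~0.08–0.10 for p = 4. p-values near the threshold
  should be read accordingly (a Bartlett-type correction is not applied,
  to keep the statistic exactly the field-standard one).
* **Single rate regime.** Rates differ between traits, not between clades;
  no OU/early-burst/lambda alternatives.
* **No confidence intervals on σ².** Interval construction for rate
  estimates is not standardised in the source literature and is omitted
  rather than guessed.
* **One tree.** Phylogenetic uncertainty (posterior tree samples) is not
  propagated; the analysis consumes a single point-estimate tree.
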