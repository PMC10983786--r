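---
title: "Multilevel superposition: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel superposition: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remsuper)
```

## The problem

Comparative studies of protein structures routinely face data with a natural
two-level grouping: all X-ray chains of one enzyme form an ensemble, several
related enzymes form a family; or ensembles arise from the ligand bound, the
crystal form, or the experimental method. The conformational variability of
such data splits into a *between-ensemble* part (how the enzymes differ from
each other) and a *within-ensemble* part (how conformations of one enzyme
vary), and conflating the two — as a single pooled principal component
analysis does — mixes, say, differences in active-site cavity size between
enzymes with a functional open/close motion shared by all of them.

remsuper estimates the two parts separately, *jointly with* the rigid-body
superposition that every Cartesian-coordinate analysis needs.

## Model

Each observed conformation is an $n \times 3$ matrix $X_{ij}$ of C$\alpha$
coordinates ($j$-th member of ensemble $i$; $\nu$ ensembles of sizes $m_i$).
A rigid transform maps it into the common frame:

$$Y_{ij} = (X_{ij} - 1_n t_{ij}^T)\, R_{ij},$$

with translation $t_{ij}$ and proper rotation $R_{ij}$ — translate first,
then rotate; every transform in the package uses this orientation. In the
common frame a two-level Gaussian random-effects model is assumed:

$$Y_{ij} = M + Z_i + E_{ij}, \qquad
  \mathrm{vec}(Z_i^T) \sim N(0, W), \qquad
  \mathrm{vec}(E_{ij}^T) \sim N(0, \Sigma),$$

where $M$ is the population mean structure, $W$ the $3n \times 3n$
inter-ensemble covariance and $\Sigma$ the intra-ensemble covariance, both
fully anisotropic. Vectorization is `vec(t(Y))`, so coordinate (atom $a$,
axis $k$) sits at row $3(a-1)+k$. Eigen-decomposition of the estimates
(`covariance_pca()`) then yields interpretable modes: the principal
components of $\hat W$ describe how ensembles differ; those of
$\hat\Sigma$ describe variability shared across ensembles after
between-ensemble differences are adjusted out.

## Estimators

Four estimators share this model family:

* **REM** (`rem_fit()`): maximum likelihood for the full random-effects
  model by EM, treating the $Z_i$ as latent. Each sweep (i) re-superposes
  every conformation onto its tentative ensemble mean $M + \hat Z_i$ with
  atom weights from the current $\hat\Sigma$; (ii) computes the Gaussian
  posterior of each $Z_i$ under the current $(W, \Sigma)$ prior — the
  empirical-Bayes step, with posterior covariance
  $V_i = (W^{-1} + m_i\Sigma^{-1})^{-1}$ and mean
  $b_i = V_i \Sigma^{-1}\sum_j (y_{ij}-\mu)$; (iii) applies the standard
  mixed-model (Laird–Ware) M-step updates of $\mu$, $W$, $\Sigma$;
  (iv) recenters the mean (gauge step). The posterior-mean deviations
  shrink small ensembles toward the population mean, which is where the
  method earns its keep: information from all ensembles stabilizes the
  superposition of an ensemble with only a handful of structures.
* **TS** (`ts_fit()`): the fixed-effects alternative — superpose each
  ensemble separately (IWLS or OLS, giving the TS/IWLS and TS/OLS
  variants), then superpose the $\nu$ ensemble means; $\hat W$ is the
  scatter of the aligned means (ML divisor $\nu$ by default) and
  $\hat\Sigma$ the $(m_i - 1)$-weighted pooled within-ensemble covariance.
* **SPE** (`spe_fit()`): ignore the grouping, superpose the pool; its
  single covariance obeys $\Delta \approx W + \Sigma$.
* **IWLS/OLS** (`iwls_superpose()` / `ols_superpose()`): the single-ensemble
  building block. IWLS iterates between superposition with per-atom weights
  and re-estimation of per-atom variances from the aligned residuals, so
  rigid cores dominate the fit and floppy termini do not drag it around.

## Numerical and algorithmic choices

These are the decisions a user may want to know about; each is a package
default with an argument to change it.

**Marginal likelihood evaluation.** The stacked covariance
$I_m \otimes \Sigma + J_m \otimes W$ is never formed: each ensemble is
split orthogonally into its mean ($\sqrt m\,\bar y \sim N(\sqrt m\,\mu,
\Sigma + mW)$) and $m-1$ within-ensemble contrasts ($\sim N(0, \Sigma)$),
so one $3n$ factorization of $\Sigma$ plus one of $\Sigma + mW$ per distinct
ensemble size suffices. `rem_loglik()` is tested against a dense
$3nm$-dimensional evaluation.

**Monotonicity guard.** The transform step uses scalar per-atom weights
(inverse mean per-atom variance of $\hat\Sigma$); under a full anisotropic
$\Sigma$ this is not an exact ascent direction for the marginal likelihood,
so a proposed transform update is kept only when the likelihood does not
decrease, and an EM sweep that cannot improve the likelihood (the flat
region near a stationary point) reverts and stops. The reported
`loglik_trace` is therefore non-decreasing by construction, and EM theory
makes the guard a no-op away from convergence.

**Ridge and initialization.** With $\nu$ or $\sum m_i$ below $3n$ — true
for most real applications — the ML covariances are rank-deficient. All
inversions use a small relative ridge ($10^{-6} \cdot \mathrm{tr}(C)/3n$ by
default). The *starting* covariances additionally receive a 10% isotropic
inflation: the raw moment estimates are degenerate spikes of the (ridged)
likelihood surface, and EM started there descends instead of ascending; an
overdispersed positive-definite start restores clean ascent.

**Initial superposition.** The default warm start is a two-stage fit
(`init = "ts_warm"`). Initializing instead from a pooled superposition
(`init = "ols_pool"`) pushes much of each ensemble deviation $Z_i$ into the
initial transforms, and EM — whose final superposition genuinely depends on
its initial one — stays in that basin, deflating both covariances by
15–25% in our experiments and spoiling the $\Delta \approx W + \Sigma$
diagnostic. The per-ensemble stage-1 superpositions of the two-stage fit
preserve the $Z_i$ and EM then refines an already-consistent configuration.
`seed` gives cheap random restarts for checking basin sensitivity.

**Moderated IWLS weights.** Pure ML weighting $w_a = 1/\hat\sigma_a^2$ is
degenerate: the transform can zero the residual of the single quietest atom,
its weight diverges, and the superposition collapses onto it — at *any*
ensemble size. Two safeguards are applied before inversion: the per-atom
variances are smoothed toward their pooled mean as if `prior_df = 4`
pseudo-observations were added (the inverse-gamma-prior idea of
heteroscedastic superposition methods), and no variance may fall below
`min_rel_variance = 0.05` of the mean atom variance, capping the weight
ratio at 20. An absolute floor of $10^{-6}\,\mathring{A}^2$ guards the
all-identical-structures edge case. The same capped rule supplies the REM
transform-step weights.

**Gauge fixing.** Superposition leaves a global translation/rotation
undefined. The mean structure is centered at the origin and its orientation
anchored to the first conformation's initial frame (single-ensemble fits)
or the warm-start mean frame (REM), making every fit deterministic given
the input order. Covariance matrices transform by conjugation with
$I_n \otimes R^T$ under a gauge rotation; `register_to_reference()` applies
this when two fits (or a fit and a simulation truth) must be compared,
because neither covariance diagonals nor eigenvectors are gauge-invariant.

**Eigenvector conventions.** Eigenvalues are clipped at zero within
$10^{-8}\cdot\mathrm{tr}$; each eigenvector's largest-magnitude component
is made positive (ties to the lowest index). Projections are in Å;
for $\hat\Sigma$ models the default projected residual is the
within-ensemble one, $y_{ij} - \hat\mu - \hat z_i$; for $\hat W$ and
$\hat\Delta$ models the total residual $y_{ij} - \hat\mu$.

## The synthetic-data generator

`make_truth()` + `simulate_ensembles()` provide the study conditions for
the recovery experiments (`recovery_experiment()`), standing in for
reference covariances derived from molecular dynamics that are not
distributable. The generator emulates:

* a globular mean chain (3D Lissajous curve scaled to a protein-like radius
  of gyration $2.2\,n^{0.38}$ Å);
* "essential dynamics" covariances: `rank` smooth collective modes with
  $1/k^2$ eigenvalue decay over a diagonal local-wiggle floor carrying
  `diag_frac = 0.3` of the variance;
* strong per-atom heteroscedasticity via a terminal-flexibility envelope
  (chain ends fluctuate several-fold more than the core);
* mean per-coordinate standard deviation scaled to 0.5 Å, the magnitude
  typical of reference variability estimates for a stable enzyme;
* rigid-body deflation of the truth in the *inverse-variance metric*
  (capped like the fitting weights): variance along rigid motions is pure
  gauge — unrecoverable by any superposition — and a reference covariance
  produced by a heteroscedastic superposition pipeline has its null space
  exactly there. Deflating in the unweighted metric instead would bias the
  comparison toward OLS-type fitters.
* conformations drawn as $M + Z_i + E_{ij}$ and then displaced by uniform
  SO(3) rotations and Gaussian translations (10 Å per component), so the
  fitters must recover the frames; the generating deviations and transforms
  are retained for oracle checks.

For recovery studies the constructed truth is additionally passed once
through the estimation pipeline itself (`calibrate_truth()`: a large sample
is drawn, fitted by heteroscedastic superposition, and the registered,
rescaled estimate becomes the truth). Reference covariances in practice
*are* such pipeline images — estimates from trajectory data — and an
analytically built truth sits slightly off that manifold; the mismatch is
invisible at small ensemble sizes but becomes the dominant error at large
ones, flattening the accuracy-vs-size curves that the recovery experiment
is supposed to exhibit.

What it does *not* emulate: missing residues and alternate conformations
(complete cases only, as the import pipeline produces), experimental noise
differences between structures, non-Gaussian tails, and anharmonic
(multi-basin) dynamics. Passing recovery tests on this generator therefore
demonstrates correct estimation under the stated model, not robustness to
model violation.

Recovery is scored on MAE of per-coordinate standard deviations
(`mae_sqrt_diag()`) and RMSIP of the leading eigenvector subspaces
(`rmsip()`), after registering each fit onto the truth frame. Experiments
in the test suite use $n = 30$ atoms, $\nu \in \{10, 40\}$ ensembles and
$m \in \{3, 10, 30\}$ members with 10 replicates — sizes chosen so the full
grid runs on one CPU in minutes while preserving the qualitative regime
$m_i < \nu$, small-sample $W$, well-sampled $\Sigma$.

## Known limitations

* All estimators inherit superposition's gauge ambiguity: $6$ of $3n$
  degrees of freedom per conformation are absorbed by the transforms, so
  covariance components along (weighted) rigid motions are estimated as
  zero. At $n$ in the tens this is a visible fraction of the trace; at
  protein sizes ($n$ in the hundreds) it is small.
* EM convergence is slow near the optimum (hundreds of sweeps is normal);
  the `tol`/`max_iter` defaults favour accuracy over speed.
* TS/IWLS can fail for tiny ensembles ($m_i = 3$) when IWLS diverges; the
  failure is flagged per ensemble and the ensemble excluded, not fatal.
* Inadequate grouping shows up as inflated $\hat W$; comparing against the
  SPE fit (whose $\hat\Delta$ ignores grouping) is the recommended check.

## A minimal session

```{r example, eval = FALSE}
truth <- make_truth(n = 30, scale = 0.5, seed = 1)
sim <- simulate_ensembles(truth, nu = 10, m = 5, seed = 2)

fit <- rem_fit(sim$set, rem_config(tol = 1e-6, max_iter = 200))
glance(fit)

pca_W <- covariance_pca(fit$W_hat, K = 2, source = "W")
scores <- project_structures(sim$set, fit, pca_W)
plot_pc_scores(scores)

profile <- per_residue_displacement(pca_W, 1, scores$PC1)
plot_displacement_profile(profile)
```
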