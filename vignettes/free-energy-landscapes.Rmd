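---
title: "Free energy landscapes by force matching: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free energy landscapes by force matching: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fesfold)
```

## The problem

A nucleosome array explores an enormous conformational space; its
thermodynamics over a handful of collective variables (CVs) is summarized
by a free energy surface (FES)

$$A(\mathbf{d}) = -k_B T \,\ln \int \delta(\mathbf{d}(\mathbf{r}) - \mathbf{d})\,
  e^{-U(\mathbf{r})/k_B T}\, d\mathbf{r} + \text{const},$$

here over the six inter-nucleosome center distances
$\mathbf{d} = (d_{12}, d_{13}, d_{14}, d_{23}, d_{24}, d_{34})$ of a
tetra-nucleosome. A six-dimensional surface is out of reach for
histogram-based estimators such as umbrella sampling, whose cost grows
exponentially with dimension because windows must overlap everywhere.
Force matching sidesteps the overlap requirement: the *mean force*

$$\mathbf{F}(\mathbf{d}_o) = \langle k\,(\mathbf{d} - \mathbf{d}_o)\rangle
  \;\xrightarrow{k \to \infty}\; -\nabla A(\mathbf{d}_o)$$

is estimated independently at each of many scattered centers
$\mathbf{d}_o$ from harmonically restrained sampling, and a smooth
surrogate $A_\theta(\mathbf{d})$ is fit by minimizing
$\frac{1}{N}\sum_o \lVert \nabla A_\theta(\mathbf{d}_o) +
\mathbf{F}(\mathbf{d}_o)\rVert^2$.

This package implements that entire workflow — collective variables,
enhanced-sampling exploration, center selection, mean forces, the
symmetry-respecting network, validation marginals, umbrella/WHAM
cross-checks, and the finite-temperature string method for most-probable
pathways — against analytic benchmark potentials sampled by overdamped
Langevin dynamics, so every stage is verifiable at desk scale. The
molecular-dynamics engine and the chromatin force field themselves are out
of scope: the CSV mean-force interchange format is the boundary where real
simulation output could be substituted.

Units throughout: nm, kcal/mol, Kelvin, with
$k_B = 0.0019872041$ kcal/(mol K).

## Collective variables

`cvlib` computes nucleosome centers as unweighted centroids of beads
labeled `core` (the rigid histone core plus inner nucleosomal DNA; the
operational definition of "center" is a package choice since none is
universal), the distance vector in fixed lexicographic pair order, the
fraction of native contacts

$$Q = \frac{1}{6} \sum_{i<j} \exp\!\left[-\frac{(d_{ij} - d_{ij}^o)^2}
 {2\sigma^2}\right], \qquad \sigma = 2\ \text{nm},$$

and the radius of gyration, unweighted over all beads (coarse-grained
beads are near-uniform; a `which = "core"` option restricts the selection
because whether flexible DNA should enter is genuinely ambiguous).

Relabeling the four nucleosomes in reverse order permutes the distance
vector as $\tilde{\mathbf{d}} = (d_{34}, d_{24}, d_{14}, d_{23}, d_{13},
d_{12})$ and must leave the free energy (essentially) unchanged.
`symmetric_features()` maps $\mathbf{d}$ to
$(d_{12}{+}d_{34},\ d_{12} d_{34},\ d_{13}{+}d_{24},\ d_{13} d_{24},\
d_{14},\ d_{23})$: sums and products are symmetric in the swapped pairs,
so the features — and any function of them — are *exactly* reversal
invariant, while (sum, product) of a positive pair still determines the
unordered pair uniquely, so no information is lost.

## Benchmark surfaces and the sampler

`make_surface()` provides analytic stand-ins with exact gradients
(finite-difference-checked in the tests): a 1-D double well
$h(x^2-1)^2$, the standard Muller–Brown potential, an $n$-D quadratic
bowl, a two-channel 2-D potential for path-clustering studies, and the
central fixture `sym6d_wells`: a reversal-symmetric 6-D Gaussian-mixture
free energy with a compact "folded" basin at
$c_f = (9, 6, 12, 9, 6, 9)$ nm, an extended "open" basin at
$c_o = (15, 25, 32, 15, 25, 15)$ nm, isotropic width 3 nm, and mixture
weights fixed so the folded basin is exactly 2 kcal/mol deeper at 300 K.
These constants are package design values chosen to caricature a compact
stacked state versus an open chain at realistic inter-nucleosome distance
scales; they are not published values.

Sampling is overdamped Euler–Maruyama Langevin dynamics,
$x \leftarrow x - (dt/\gamma)\nabla A + \sqrt{2 k_B T\, dt/\gamma}\,\xi$.
Overdamped (not underdamped) dynamics suffices because only equilibrium
statistics enter mean forces and string sampling. The integrator is
compiled (Rcpp) and draws from R's RNG, so a `set.seed()` makes
trajectories bit-reproducible. Stability requires
$dt \lesssim 0.1\,\gamma/\kappa_\max$; restrained-sampling helpers derive
their default `dt` from the spring constant this way, and the integrator
aborts with a labeled instability error if a coordinate leaves the domain
by 10 times its span.

## Exploration: metadynamics + TAMD

To collect configurations everywhere the system can plausibly go, the
physical coordinates (at $T$) are tethered by springs
$\kappa_{\mathrm{ext}}$ to extended variables $z$ evolved at a high
temperature $\bar{T}$ (TAMD), while repulsive Gaussian hills deposited at
the visited $z$ penalize revisiting (metadynamics; plain hills by
default, a well-tempered factor is available). Collective variables are
coordinate projections — the toy surfaces already live in CV space.
Defaults for the 6-D benchmark: CVs $(d_{13}, d_{24})$,
$\kappa_{\mathrm{ext}} = 2$ kcal/mol/nm², $\bar{T} = 3000$ K, hills of
0.3 kcal/mol and width 1.5 nm every 250 steps, $dt = 0.02$, and soft
harmonic walls ($k = 50$ kcal/mol/nm²) keeping $z$ inside the surface
domain — without walls the bias eventually drives distances negative.

One long biased run covers the inter-basin channel unevenly: its single
hill history carves one particular escape route, and we found the learned
surface then misjudges the *relative depth* of the two basins by a couple
of kcal/mol even when the held-out force correlation looks excellent.
The default protocol is therefore 20 independent replicas of $10^5$ steps
with separate hill histories (`explore_replicas()`), pooled before center
selection — the same replica logic the exploration literature uses, at
desk scale.

## Centers and mean forces

`select_centers()` runs K-means (deterministic k-means++ seeding under a
given seed, then Lloyd iterations via `stats::kmeans`) on the pooled
biased samples — centers concentrate where the system actually goes,
which is precisely why no center-to-center overlap is needed. The
benchmark uses 2000 centers from 50,000 subsampled points.

`estimate_mean_force()` implements the restrained estimator with an
isotropic scalar spring (per-component springs optional), 20% burn-in and
batch-means standard errors (20 batches). On a quadratic surface
$\frac{\kappa}{2}(x-\mu)^2$ the restrained ensemble is Gaussian and the
estimator has the closed form
$F = k\kappa(\mu - x_o)/(k + \kappa)$: biased toward zero by the factor
$k/(k+\kappa)$, vanishing as $k \to \infty$. The tests verify both the
values and the $\propto 1/(k+\kappa)$ decay of the bias. For benchmark
surfaces, `noisy_reference_forces()` instead evaluates the exact negative
gradient and adds Gaussian noise with SD equal to 5% of the pooled force
RMS — the benchmark's model of the statistical uncertainty real
restrained simulations would carry.

## The force-matching network

`fesnet()` fits a multilayer perceptron
(features → 64 → 64 → 1, tanh) on the symmetric features, standardized to
zero mean/unit variance over the training centers (the raw feature scales
span 6–1000 in mixed units of nm and nm²). tanh rather than a
piecewise-linear activation keeps $\nabla A_\theta$ continuous, which the
string method requires. The loss is purely on gradients, so its weight
gradient passes *through* the input-gradient computation; this
double-backprop is implemented analytically in vectorized R and verified
against finite differences in the test suite. Training: full-batch Adam
(lr $3\times10^{-3}$), L2 weight decay $10^{-5}$, a 20% held-out split
driving early stopping with patience 150 (held-out records never enter
weight updates), up to 8000 epochs — the cap and patience were set where
the held-out force loss genuinely plateaus on the benchmark; overfitting
risk is real because force noise is correlated with nothing, and the
held-out force correlation is the reported quality metric.

Because only gradients are fit, the energy is a gauge quantity; the
minimum over training centers is shifted to zero before serialization.
The network is only constrained near data: `fes_trusted()` declares a
point trusted within a cutoff (twice the 95th percentile of
nearest-neighbor distances among training centers) of some center, and
every downstream integral is restricted to the trusted domain — a learned
surface evaluated outside it is extrapolation and is flagged, never
silently used.

## Validation: marginals and WHAM

`marginal_profile()` integrates $e^{-A_\theta/k_B T}$ over the remaining
dimensions by uniform Monte-Carlo over the trusted-domain bounding box
with rejection of untrusted points, points shared across grid values
(common random numbers), per-cell delta-method standard errors, and cells
with (near-)zero trusted volume reported as missing. The oracle
`marginal_1d_exact()` does the same integral on the *analytic* surface:
tensor Gauss–Legendre quadrature when at most 3 dimensions are
integrated, seeded Monte-Carlo with reported standard error above that.
`compare_profiles()` aligns the additive offset on common support before
reporting deviations, since free energies are only defined up to a
constant.

The independent cross-check mirrors the classical route: umbrella
sampling along one distance (default: 3 pooled replicas per window,
because rugged orthogonal degrees of freedom can trap neighboring
windows in different basins) recombined by the standard WHAM
self-consistent iteration, converged when window offsets move by less
than $10^{-6}$ kcal/mol. Empty bins stay empty — reported as missing
rather than regularized, which would silently bias low-count regions.

On the benchmark, the trained network's held-out force correlation is
about 0.99 and its $d_{13}$ marginal tracks the exact one within about
0.2 kcal/mol; the quality bars adopted by the package's acceptance tests
(correlation $\ge 0.87$, marginal agreement within 1 kcal/mol) are the
published force-matching quality levels for this class of problem, and
the numbers above are recomputed — not asserted — by
`scripts/acceptance.R` and the test suite.

## Folding pathways: the finite-temperature string method

`fts_relax()` discretizes a path into $M+1$ images and iterates:
Langevin sampling restricted to each image's Voronoi cell (proposals
whose nearest image is another cell are rejected — simple, and it samples
the cell-restricted Boltzmann law exactly), image moves toward the cell
mean with step $\alpha = 0.1$, smoothing of interior images with
$\lambda = 0.1$, and equal-arc-length reparameterization. Endpoints stay
fixed at the supplied minima by default (a relaxed-endpoint mode exists;
which the published calculations used is not stated, so both are
provided). Convergence is declared when the maximum image displacement
drops below `tol`; with stochastic cell means the displacement cannot
fall below the sampling noise floor $\sim \alpha\,\sigma_{\rm
cell}/\sqrt{n}$, so `tol` should be set accordingly (defaults: $M = 32$,
`tol` $10^{-3}$ in CV units for the 2-D potentials, 0.02 nm for the 6-D
benchmark).

Finite temperature matters: the method averages over fluctuations of
order $k_B T$ and so reveals the transition *tube* rather than the
zero-temperature minimum-energy path; at small $T$ the two coincide, and
the tests verify on Muller–Brown that the relaxed string passes through
the intermediate minimum located independently by a dense-grid search.
`string_multistart()` mirrors the multi-initialization protocol (default
8 desk-scale starts, waypoint-seeded) and `cluster_paths()` groups the
results into distinct channels by single-linkage on the mean
image-to-image distance.

## What the synthetic benchmark does and does not show

The `sym6d_wells` benchmark exercises every algorithmic claim —
symmetry enforcement, noise robustness of force matching, trusted-domain
marginals against an exact oracle, WHAM cross-validation, multi-channel
path finding — under conditions (distance scales, basin separation,
barrier heights of a few kcal/mol, 5% force noise, 2000 centers) chosen
to resemble the chromatin application. It does **not** emulate: rugged
small-scale structure from a molecular force field (its basins are smooth
Gaussians), anisotropic or correlated force-estimation noise, the
approximate (rather than exact) reversal symmetry of a non-palindromic
DNA sequence, or CVs that are nonlinear functions of the sampled
coordinates. Passing here shows the machinery is correct and calibrated,
not that any particular molecular system is within reach.

## Numerical choices collected

* Quadrature: Gauss–Legendre, 40 nodes per integrated dimension (≤ 3
  dims); uniform MC with common random numbers above that.
* Monte-Carlo sizes: 2×10⁴ points per cell for model marginals, 4×10⁵
  for the exact 5-dim marginal; chosen so MC noise (standard errors
  ~0.03–0.1 kcal/mol) is small against the 1 kcal/mol agreement bar.
* K-means: k-means++ seeding, Lloyd, 30 iterations; assignment ties go to
  the lowest center index.
* WHAM: 100 bins default, tolerance $10^{-6}$ kcal/mol on offsets;
  single-window zero-spring input reduces exactly to the histogram
  estimate (tested).
* Degenerate inputs: coincident nucleosome centers yield a flagged zero
  distance; coincident string endpoints are an error; an empty center set
  returns an empty record table; cells with no trusted volume are
  missing, not zero.
* Problem sizes: the shipped defaults (20×10⁵ exploration steps, 2000
  centers, 8000-epoch cap, 61-point marginals) run the full benchmark in
  roughly ten minutes on one core; every size is a config value and
  production-scale analogues (10⁴ centers, 70 string starts) are
  reachable by configuration alone.

## Known limitations

* Mean-force standard errors from batch means assume the batch length
  exceeds the correlation time; very stiff restraints with long memory
  would need thinning.
* The trusted domain is a union of balls — a crude envelope that can
  include unsampled pockets between centers; density-aware envelopes
  would be tighter.
* Marginal Monte-Carlo uses uniform proposals; importance sampling is
  left as an option and would be needed if the trusted box were much
  larger than the region of appreciable Boltzmann weight.
* The compiled samplers support projection CVs; arbitrary differentiable
  CV functions would require either R-callback sampling (slow) or user
  C++ extensions.
* No uncertainty quantification on the learned surface beyond held-out
  correlation; ensembles would be the natural extension.
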