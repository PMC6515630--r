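---
title: "A finite-size coil-globule model for epigenetic domain folding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A finite-size coil-globule model for epigenetic domain folding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Super-resolution microscopy yields, for each epigenetic domain of a genome
(in *Drosophila*: active, inactive and Polycomb-repressed chromatin
*colors*), the full per-cell distribution of the squared radius of gyration
$R_g^2$ rather than a single average. `chromocoil` turns those
distributions into physical chromatin parameters: the effective
nucleosome-scale interaction energy per Kuhn segment $\varepsilon$ (in
$k_BT$), the Kuhn length both in base pairs ($K_{bp}$) and nanometers
($K_{nm}$), their ratio the linear compaction $c = K_{bp}/K_{nm}$, and the
geometry of the "bundle" formed by unresolved paired homologous chromosomes
in tetraploid cell lines.

The central idea is that a domain of genomic length $L$ behaves as a
self-attracting polymer of $N = L/K_{bp}$ Kuhn segments near its
coil-globule transition, where *finite-size effects* dominate: instead of
the sharp asymptotic transition at the theta point
$\varepsilon_\theta \simeq 0.27\,k_BT$, finite chains show a gradual
crossover with a characteristic knee in $\bar R_g(N)$, and small and large
domains of the same color can sit on different sides of it.

## The model

### Free energy and the distribution of $R_g^2$

All lengths are measured in Kuhn units. With the monomer density
$\rho = N/R_g^3$ and the renormalized density $t = \rho^{1/(\nu d - 1)}$
($d = 3$), the free energy of a chain of $N$ segments is

$$\beta F_N(t \mid \varepsilon) = a_1(\varepsilon)\,N t
  + a_2(\varepsilon)\,N t^2 + a_3(\varepsilon)\,(N t)^{-2/3}
  + a_4(\varepsilon)\,(N t^2)^{2/3} - c \ln(N t), \qquad c = -1.13 .$$

$a_1$ is a second virial coefficient (vanishing at the theta point), $a_2$
a three-body term dominant in the globule, $a_3$ the elastic penalty of
extended conformations, $a_4$ a surface term important in the crossover,
and the fixed logarithmic term carries the self-avoiding-walk enhancement
exponent. The observable's density is
$P_N(R_g^2 \mid \varepsilon) \propto e^{-\beta F_N}$, normalized
numerically, and the dimensional density for a domain of $L$ bp is
$P_L(R_g^2) = K_{nm}^{-2} P_{N}(R_g^2/K_{nm}^2)$ with $N = L/K_{bp}$
(`pdf_rg2_dimensional()`). $N$ is treated as a positive real number — the
mapping $N = L/K_{bp}$ forces fractional values.

**Which $\nu$ enters the renormalization.** The exponent $1/(\nu d - 1)$ is
evaluated with the Flory self-avoiding-walk value $\nu = 3/5$, so
$t = \rho^{5/4}$. This choice is self-consistent with the functional form:
with $t = \rho^{5/4}$ the minimum of $\beta F$ reproduces exactly
$\bar R_g \propto N^{3/5}$ for $a_1 > 0$, $N^{1/2}$ at $a_1 = 0$, and
$N^{1/3}$ for $a_1 < 0$ at large $N$. Other conventions (0.588, or
regime-dependent values) would break the second of these identities. The
value is a package constant, not a tunable.

### Numerical choices

* **Quadrature support.** $R_g^2 \in [0.15\,N^{2/3},\, N^2/4]$. The upper
  bound is the rod limit. The lower bound deserves a comment: on a cubic
  lattice, a *filled-ball* globule has $\rho = N/R_g^3 \approx 9\phi$ for
  site-filling fraction $\phi$, because the gyration radius of a uniform
  ball is much smaller than its radius. A lower bound at $\rho \le 1$
  (i.e. $R_g^2 \ge N^{2/3}$) would therefore cut off real dense-globule
  configurations; the factor 0.15 places the bound at $\rho \approx 17$,
  safely beyond physical close packing, while keeping the integrable
  domain finite.
* **Quadrature rule.** Composite Simpson on a grid uniform in
  $u = \ln R_g^2$ (the substitution makes the spacing uniform and the
  error $O(h^4)$), with one support-shrinking pass that restricts the grid
  to the region where the relative density exceeds $10^{-20}$ — essential
  for long chains, whose density occupies a narrow slice of the full
  support — followed by grid doubling until the normalization is stable to
  $10^{-8}$. Densities evaluated this way integrate to 1 to better than
  $10^{-6}$ under an independent adaptive quadrature (asserted in the test
  suite).
* **Coefficient interpolation.** $a_1..a_4$ are tabulated on the
  calibration energy grid and interpolated with a monotone (Fritsch-Carlson)
  cubic; evaluating outside the grid raises an error. The coefficients are
  only empirically known — silent extrapolation would fabricate physics.

### Bundle correction for tetraploidy

Unresolved paired chromosomes add an independent, exponentially distributed
offset $B^2$ with mean $\sigma^2(N)$ to every measured $R_g^2$
(`bundle_density()`, Eq. mean $\langle R_g^2\rangle_{obs} =
\langle R_1^2\rangle + \sigma^2$). The section spreading interpolates
between $a_0$ (short chains) and $a_\infty$ over a crossover scale $N_0$;
the constant-section variant $\sigma \equiv a_0$ is used where the full
form degenerates (repressed domains, whose fitted $N_0$ and $a_\infty$
diverge). The observed density is the convolution $P_L * f_\lambda$,
computed *exactly* for the piecewise-linear interpolant of $P_L$ against
the exponential kernel — a closed form stable for any $\sigma$, including
the delta-kernel limit $\sigma \to 0$. The implementation takes the
unshifted exponential at face value: the apparent "shift" in the smallest
domains' distributions is carried by the single-polymer factor of the
convolution, not by a shifted kernel. The chain count of the bundle
(tetraploid, ~80% pairing) never enters: the data constrain only the
scalar $B^2$ law.

Deconvolution (`deconvolve_mean()`) inverts the mean additivity to produce
haploid curves; `estimate_bundle_from_small_domains()` fits the exponential
rate on the pooled $R_g^2$ of the shortest domains (default: the shortest
decile of domain lengths — the study does not state its threshold; the
argument is exposed), with a percentile bootstrap for the confidence
interval.

## Lattice calibration

The coefficients are calibrated on interacting self-avoiding walks (ISAW)
on the simple cubic lattice, with energy $-\varepsilon$ per non-bonded
nearest-neighbour contact. One lattice monomer is one Kuhn segment, which
makes the lattice $\varepsilon$ directly comparable to the fitted chromatin
$\varepsilon$ and places the theta point at the known
$\varepsilon_\theta \approx 0.278\,k_BT$.

* **Move set.** 20% pivot moves (a random proper octahedral rotation about
  a random internal site, applied to the shorter arm) and 80% local moves
  (end rotation, corner flip, crankshaft), Metropolis acceptance
  $\min(1, e^{\varepsilon \Delta C})$ on the contact count $C$. A sweep is
  $N$ attempted moves. Incremental contact bookkeeping is audited against a
  full recount every $10^3$ accepted moves when `audit = TRUE`.
* **Burn-in and annealing.** Default burn-in $\max(400, 4N)$ sweeps;
  across the energy grid each chain starts from the final configuration of
  the previous (lower) energy, which keeps dense globular states
  equilibrated at a fraction of the cost. Seeds derive from the master seed
  by a stated splitting rule (`grid_seed()`), so grids are bitwise
  reproducible.
* **Shipped calibration.** `default_coefficients()` loads the table
  calibrated on $N \in \{16, 32, 64, 128, 256, 512\}$, fifteen energies
  from 0 to 0.6, 2000 recorded samples per cell (the metadata records
  seeds, sample counts and per-energy goodness of fit). Coefficients are
  fitted per energy by maximizing the joint likelihood of the samples
  across all chain lengths, with $c$ fixed at $-1.13$ and $a_2, a_3$ kept
  positive via log parameterization; a magnitude-spanning multi-start
  battery plus continuation in $\varepsilon$ guards against the stretched,
  multi-modal likelihood surface.

### Identifiability of $a_1$ and the two theta estimators

Over a finite range of chain lengths the coil-regime density depends on
$N$ and $R_g^2$ essentially through the reduced variable
$x = R_g^2/N^{6/5}$, in which both the $a_1$ and $a_3$ terms are pure shape
terms ($a_1 x^{-15/8}$ and $a_3 x^{5/4}$): they are nearly exchangeable,
and the fitted $a_1$ near the theta point is weakly identified. Two
estimators of the theta energy are therefore provided and kept distinct:

1. `locate_theta()` on a coefficient set: the zero crossing of
   $a_1(\varepsilon)$. With the shipped calibration ($N \le 512$) this
   crossing is systematically *below* the true theta point — at the true
   theta the model needs slightly negative $a_1$ to hold random-walk
   scaling over a finite $N$ window — and should be read as a structural
   marker, not a precision estimate.
2. `locate_theta()` on a calibration grid: the energy where the log-log
   slope of $\langle R_g^2\rangle$ versus $N$ crosses 1 (equivalently,
   where $\langle R_g^2\rangle / N$ is $N$-independent). This is the
   estimator used for the headline theta-point measurement; at
   $N \le 400$ it carries the opposite (positive, finite-size) bias of a
   few hundredths of $k_BT$.

## Bayesian inference

For one color, the total log-likelihood sums $\ln (P_L * f_\lambda)$ over
all domains and cells (`total_log_likelihood()`), and the posterior under a
positivity-enforcing uniform prior box is sampled with the Goodman-Weare
affine-invariant ensemble sampler, implemented in `stretch_sampler()`
(stretch moves, $a = 2$, two half-ensemble sweeps per step). Affine
invariance matters here because the coil-regime posterior concentrates on
a strongly correlated power-law ridge in $(K_{bp}, K_{nm})$.

Default settings (the study reports none): walkers $= 8 \times$ dimension,
burn-in half the chain, prior box $\varepsilon \in (0, 1]$,
$K_{bp} \in (100, 2\times10^4]$ bp, $K_{nm} \in (5, 300]$ nm,
$a_0, a_\infty \in (1, 1000]$ nm, $N_0 \in (1, 5000]$, with
$a_\infty \ge a_0$ and $\varepsilon$ clipped to the calibrated coefficient
range. The model variant (`full` six-parameter vs `constant_bundle`
four-parameter) is explicit configuration, never auto-selected; the
constant variant is the recommended model for repressed domains.

For active (coil-regime) data the marginal means of $K_{bp}$ and $K_{nm}$
are ill-defined — the likelihood is flat along
$K_{nm} = \kappa K_{bp}^{\nu}$ — so `fit_ridge()` reports the ridge
$(\kappa, \nu)$ by total least squares in log-log space (first principal
component), with bootstrap errors, and warns when the posterior is not
actually ridge-degenerate ($|r| < 0.5$ in log space). The two-angle module
then turns the ridge into point estimates: substituting
$K_{bp} = c\,K_{nm}$ gives the data curve $K_{nm}(c)$, whose intercept
with the geometry-based $K^{geom}_{nm}(c)$ curve selects a compaction.

## Two-angle fiber plausibility module

`fiber_spec()` maps a wrapping angle ($+50^\circ$ fully wrapped to
$-30^\circ$ open) to wrapped DNA by a linear convention (147 bp at
$+50^\circ$, 1 bp per degree — the published angle convention is only
qualitative, so the map is an explicit, replaceable configuration), and
the entry-exit deflection between successive linkers linearly from
$0^\circ$ (collinear) at $-30^\circ$ to $150^\circ$ at $+50^\circ$.
Nucleosomes are points joined by straight rigid linkers (0.34 nm/bp);
linker torsion follows the 10.5 bp/turn helical repeat. The geometric Kuhn
length uses the freely rotating chain relation $K = b(1+g)/(1-g)$ with
$g = \cos(\text{deflection}) \cdot e^{-b/P}$, i.e. the deterministic
deflection attenuated by worm-like decorrelation along the linker
($P = 50$ nm DNA persistence length; nucleosome body rigid). This is
deliberately the simplest defensible estimator — the module checks
plausibility of parameters obtained independently by the polymer fit, and
the estimator is pluggable.

## Synthetic data

`synthetic_spec()` encodes the study design: 23 active, 14 inactive and 11
repressed domains, each observed in a uniform 20-100 cells, per-color
generating parameters at the headline fitted values (active
$\varepsilon = 0.10$, $K_{bp} = 1300$, $K_{nm} = 35$, bundle 130/290/630;
inactive 0.32, 3900, 60, bundle 93/170/10; repressed 0.44, 1500, 37,
constant bundle 94 nm). Domain lengths are log-uniform in 15-500 kb — the
study prints only domain counts, so a scale-free sampler over the observed
length range is the neutral choice; a list override exists for targeted
experiments. Ground truth is always written alongside and must only be
read for scoring, never during fitting.

What the generator does *not* emulate: localization error and other imaging
noise (not modeled by the analysis either), genomic heterogeneity of
parameters within a color, and inter-domain correlations. Passing recovery
tests therefore show the estimator is consistent under the model's own
assumptions — not that real chromatin satisfies them.

The enrichment-trace utilities plant boxcar domains plus i.i.d. noise and
call candidates with a moving-average filter whose window *equals* the
candidate length $L$ (the window is part of the definition, not a free
parameter).

## Problem sizes and verification

The test suite runs at desk scale: four-site exact enumeration against the
sampler; SAW scaling at $N \le 256$; theta location from a fresh grid at
$N \le 384$; parameter recovery and ridge fits on reduced synthetic
datasets (6-8 domains, 25-30 cells) with 16-32 walkers and a few hundred
ensemble steps. The acceptance script simulates $N \le 400$ over
$\varepsilon \in [0.20, 0.35]$ with 1200 samples per cell. These sizes were
chosen so each stage's statistical error stays well inside the tolerances
being asserted; the shipped calibration was produced at the larger sizes
stated above.

## Known limitations

* The $a_1$ zero crossing is a biased theta estimator at the calibrated
  chain lengths (see above); the grid-slope estimator carries the opposite
  bias. Both are reported rather than hidden.
* Per-energy coefficient fits are not unique (the $a_1$/$a_3$ degeneracy);
  the shipped table is one valid representative whose *densities* are the
  calibrated object. Regularized variants (`share_elastic = TRUE`) trade
  globule-side fit quality for smoother virial coefficients and are not
  the default.
* The bundle model reduces tetraploidy to a scalar exponential offset;
  allele-resolved structure is out of scope.
* The two-angle module is a plausibility check with a configurable angle
  convention, not a crystallographic model.
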