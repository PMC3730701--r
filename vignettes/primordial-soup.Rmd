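---
title: "A synthetic primordial soup: model, blanket discovery and free-energy checks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A synthetic primordial soup: model, blanket discovery and free-energy checks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`primsoup` simulates an ensemble of coupled stochastic subsystems — a
"primordial soup" — and runs the analysis chain that exposes the lifelike
organisation buried in it: spectral recovery of the principal Markov blanket
from the contact graph, a canonical-variates test that internal dynamics
predict external motion against a time-reversal null, lesion experiments
probing self-maintenance, and constructive verification of the variational
free-energy lemma on tractable linear-Gaussian systems.  This vignette is
the package's own account of the model, the numerical choices, and what the
shipped defaults do and do not establish.

## The ensemble model

Each of `n` subsystems carries two kinds of state.  *Structural* states are
a position and velocity in a `d`-dimensional Euclidean space (two
dimensions by default).  *Functional* (electrochemical) states are a
3-vector `x = (x1, x2, x3)` whose deterministic flow has the Lorenz form,
scaled by a per-subsystem rate constant `kappa`:

    dx1/dt = kappa * sigma * (v2 - x1)
    dx2/dt = kappa * (rho * v1 - x2 - v1 * x3)
    dx3/dt = kappa * (v1 * x2 - beta * x3)

with the canonical parameters `(sigma, rho, beta) = (10, 32, 8/3)`.  Here
`v = (v1, v2, v3)` is the *local average* of the electrochemical states
over the subsystem itself and its in-neighbours — the subsystems within the
coupling radius (one length unit) whose influence has not been switched
off.  The local average enters the flow both linearly and nonlinearly, so
the effective Rayleigh parameter of each subsystem is modulated by its
neighbourhood, `v1 * (rho - x3)`; this is what permits generalized
synchronization between coupled subsystems.  An isolated subsystem (whose
local average is its own state) follows the textbook Lorenz equations — a
property the test suite checks against an independently coded integrator.

The rate constants are drawn once at initialisation as
`kappa = 2^(-2 * U^8)` with `U ~ Uniform(0, 1)`: most subsystems are fast
(`kappa` near one) and a few are up to four times slower.  This is the
package's parameterisation of rate heterogeneity; any map of `U` with a
heavy mass near one and a slow tail produces the same phenomenology.

A random third of the subsystems (`round(n * closed_fraction)`) is rendered
*functionally closed*: their column of the contact adjacency matrix is
zeroed, so they sense their neighbours but cannot influence anyone's
electrochemical states.

Newtonian motion is driven by four forces:

* **pairwise repulsion** — inverse-square in the near field, Gaussian-
  screened beyond about two coupling radii (`exp(-r^2 / 2 * (2 rho)^2)`).
  The screening keeps every interaction short-range, which is the premise
  that makes remote subsystems conditionally independent in the first
  place; an unscreened Coulomb tail couples arbitrarily distant clusters
  and (empirically) holds sub-clusters permanently apart, fragmenting the
  ensemble into disconnected islands;
* **pairwise attraction** — a weaker, short-range bond with radial profile
  `(r/rho) * exp(-r^2 / 2 rho^2)` (peaking at the coupling radius), gated
  by the *coherence* of the pair's third electrochemical states:
  `c = (s^2 - dz^2) / (s^2 + dz^2)` with `dz = x3_i - x3_j` and coherence
  scale `s = 8`.  Subsystems whose third states agree attract; discordant
  pairs repel.  The bond is a *reciprocal electrochemical exchange*: a pair
  involving a functionally closed subsystem forms no bond at all, applied
  symmetrically so that every pairwise force satisfies Newton's third law
  exactly.  This is the package's reading of closure: a closed subsystem
  cannot exert electrochemical influence, so it cannot participate in the
  chemistry that binds neighbours.  The choice is load-bearing — direct
  measurement shows that a closed subsystem *one-way synchronises* to its
  local field as well as open subsystems synchronise mutually (median
  neighbour `|dz|` about 0.57 versus 0.58), so no coherence gate alone can
  distinguish them.  Without bond reciprocity, closed subsystems are
  neither expelled to the periphery nor does lesioning produce dispersal;
* **viscous drag** `-nu * velocity`; and
* a **quadratic potential well** `-k * position` that draws the whole
  ensemble to the origin so that local interactions actually happen.

Integration is forward Euler (Euler–Maruyama) with steps of 1/512 s.
Unit-variance Gaussian increments scaled by `noise_sd * sqrt(dt)` enter the
velocity and electrochemical equations (not the position equation, which is
slaved to the velocity).  Pair distances in the force law are clamped below
at `1e-6`; clamped encounters are counted and reported — physically these
are the near-collisions that the inverse-square law blows apart.  The
contact adjacency is recomputed from the current positions at every step.
Non-finite states abort the run with the time and subsystem index.

### Default force constants

The displayed default constants — repulsion 1, attraction 2, viscosity 12,
well stiffness 1/8 — were fixed once so that the default ensemble is a
"restless soup": the subsystems fall to the bottom of the well, bind into a
single jostling cluster with neighbour spacing near the coupling radius,
and keep a quasi-stable contact graph over hundreds of seconds while the
electrochemical dynamics burst and synchronise.  Far outside this regime
the ensemble is either a gas (no contacts) or a collapsing clump; both are
easily reached by halving the attraction or the viscosity, and neither
supports a meaningful blanket analysis.

## Markov blanket discovery

The contact adjacency over a trailing window (256 s by default) is the
element-wise OR of the per-frame adjacencies: two subsystems are coupled if
they touched at least once, which accommodates the adjacency being itself a
stochastic process.  With columns encoding influence *from* each state, the
Markov blanket matrix

    B = A + A' + A'A

has, in row `i`, exactly the parents, children and parents-of-children of
`i` — its Markov blanket.  `B` is symmetric (the transpose of `A + A'` is
itself, and `A'A` is symmetric), so the eigendecomposition is real without
any symmetrisation step.  The principal eigenvector is non-negative by
Perron–Frobenius; its entries measure membership of the most interconnected
cluster.  The `k = 8` largest entries define the internal states (ties
broken by lowest index, logged); the support of `B %*% chi` minus the
internal set is their blanket; blanket members with an incoming edge from
some external subsystem are sensory, the rest active; everything else is
external (hidden).  `verify_blanket()` confirms the defining property: no
direct edge between internal and external states in either direction.

Two caveats are worth stating.  If the windowed graph is disconnected the
principal eigenvector lives on the component with the largest eigenvalue
(a warning is emitted when the top eigenvalues are nearly degenerate), and
an empty graph is an error rather than a degenerate partition.  Second, at
reduced ensemble sizes the *sensory* class can be very small: the closed
subsystems — whose influence columns are zero — are expelled to the
periphery and form much of the structure's immediate surroundings, so few
blanket members receive influence from any open external subsystem.  This
is a genuine property of the reduced-scale geometry, not of the labelling
rule; it grows away at larger `n`, where an open external milieu surrounds
the blanket.

## Self-organized perception

The internal states' electrochemical series over the trailing analysis
window (512 s by default, on the 1 s frame grid) are temporally embedded at
lags of ±16 s (33 lags per channel) and summarised by the first 32
eigenvariates — left singular vectors scaled by their singular values, with
a deterministic sign convention (largest-magnitude loading positive).  For
each external subsystem, a canonical variates analysis asks whether a
linear mixture of those eigenvariates predicts its position (both spatial
coordinates, used as-is with no detrending).  Significance uses Wilks'
lambda, the product of one minus the squared canonical correlations, with
Bartlett's chi-squared transformation
`-(T - 1 - (p + q + 1)/2) * log(Lambda)` on `p * q` degrees of freedom.
Covariance blocks are ridge-regularised with `1e-8 * trace/dim` — the
embedded internal series are strongly collinear and the ridge is logged in
the result's metadata rather than silently applied.

The null repeats the identical analysis after reversing the external
series in time, which destroys any coupling with the internal states while
preserving each series' own correlation structure.  The largest null
statistic is the threshold; the number of true statistics strictly above it
is referred to an upper binomial tail with per-trial rate `1/n_external`.
The strictly-greater convention is deliberate:
`exceedance_pvalue(5, 82) = 0.00052` to two significant figures, and a
greater-or-equal convention gives a different number.  The brute-force
binomial sum appears as the oracle in the test suite.

## Autopoiesis and lesions

A lesion renders every subsystem with a target label (sensory, active or
internal) functionally closed from the end of a trajectory onward, leaving
positions, velocities and electrochemical states untouched; a control arm
continues the identical state with the same random stream, so differences
are attributable to the lesion alone.  Structural integrity is summarised
by the mean distance of the internal-plus-blanket subsystems from their own
centroid; the report carries the dispersion time series, the
final-over-initial dispersion ratio, and an extrusion count (internal
subsystems that end farther from the centroid than the median blanket
radius).  Because closing a subsystem severs its attractive bonds, internal
or active lesions dissolve the cohesion of the core and the structure
disperses — the dynamical-systems phenomenon of oscillator death.  A
sensory lesion at reduced scale closes only the handful of sensory-labelled
subsystems and its effect on the dispersion ratio is correspondingly small,
often within the seed-to-seed noise of the control arm (see the caveat
above about small sensory classes).

## Free-energy verification

The `fep_core` layer verifies, constructively and on systems where every
quantity has a closed form, the chain of results that motivates the
blanket analysis:

* a flow in Helmholtz standard form `f = -(Gamma + R) grad G`, with
  `Gamma` symmetric positive semi-definite and `R` exactly antisymmetric
  (the constructor rejects `||R + R'|| > 1e-12`), leaves `p = exp(-G)`
  stationary under the Fokker–Planck operator.  The residual
  `div(Gamma grad p - f p)` is evaluated with central differences on a
  uniform grid and must shrink at second order under grid refinement —
  and demonstrably fails to vanish when the circulation is corrupted into
  a non-antisymmetric matrix;
* simulating that flow with Euler–Maruyama (fluctuation covariance
  `2 Gamma`) and thinning heavily reproduces `exp(-G)` empirically
  (chi-squared goodness of fit on equiprobable bins of each marginal);
* for a joint Gaussian over (external, sensory, active, internal)
  coordinates, the variational free energy
  `F = E_q[G] - H[q]` of a Gaussian `q` over the external block upper-
  bounds the negative log evidence of the remaining coordinates, with gap
  exactly the Kullback–Leibler divergence from `q` to the exact
  conditional; minimising `F` by BFGS over the mean and log-Cholesky
  covariance recovers that conditional to `1e-6` and attains
  `F = -log evidence`.  The linear-Gaussian family is used deliberately:
  it is the largest family in which "variational optimum equals posterior"
  is an assertable identity rather than an approximation claim.

## What the tests do and do not show

The shipped test suite runs the full pipeline at a reduced scale — 64
subsystems for 512 simulated seconds, window 256 s, eight internal states,
with 256 s lesion continuations over five seeds — alongside exhaustive
combinatorial checks of the blanket matrix (every digraph on up to five
nodes, plus random digraphs to twelve nodes against a set-construction
oracle), calibration of the chi-squared under independence, and the
free-energy identities above.  Stochastic properties (rustication of closed
subsystems to the periphery, absence of closed internal states, lesion
effects) are asserted as majorities or medians over seeds, not per-run
certainties: single realisations of this system are not reproducible
objects, only its statistics are.  The generator emulates the study
conditions (unit-variance noise, 1/512 s steps, a third closed) but no
claim is made that any particular realisation reproduces any particular
published figure, and the simulator's internal states are never checked
against exact posteriors — that comparison is intractable for the soup and
is exactly why the tractable linear-Gaussian verification exists.

## Reproducibility

Every source of randomness flows from the configuration seed through R's
generator, including the compiled integrator (which draws its increments
from the same stream); identical configurations yield bit-identical
trajectories.  Analysis stages are deterministic given their inputs, and
each CLI subcommand writes a manifest (config, seed, package version,
logged decisions) alongside its output.
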