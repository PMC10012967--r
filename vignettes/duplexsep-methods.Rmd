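---
title: "Methods: a two-layer adaptive phase-oscillator model of sepsis"
author: "duplexsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-layer adaptive phase-oscillator model of sepsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexsep)
```

## The model

`duplexsep` simulates a functional network model of sepsis: a duplex
(two-layer multiplex) network of $N$ phase oscillators per layer.  Layer 1
is the parenchyma — the functional tissue of an organ — whose oscillators
represent cellular metabolic rhythms.  Layer 2 is the stroma/immune layer.
Cytokine signalling is not modelled as concentrations but as *adaptive
coupling weights* $\kappa^\mu_{ij} \in [-1, 1]$ carrying information flow
between cells.  The dynamics are

$$\dot\phi^1_i = \omega^1 - \frac{1}{N}\sum_{j \ne i}
  \left(a_{ij} + \kappa^1_{ij}\right)\sin(\phi^1_i - \phi^1_j + \alpha^{11})
  - \sigma \sin(\phi^1_i - \phi^2_i + \alpha^{12}),$$
$$\dot\phi^2_i = \omega^2 - \frac{1}{N}\sum_{j \ne i}
  \kappa^2_{ij}\sin(\phi^2_i - \phi^2_j + \alpha^{22})
  - \sigma \sin(\phi^2_i - \phi^1_i + \alpha^{21}),$$
$$\dot\kappa^\mu_{ij} = -\epsilon^\mu\left(\kappa^\mu_{ij}
  + \sin(\phi^\mu_i - \phi^\mu_j - \beta)\right),$$

with fixed all-to-all parenchymal adjacency $a_{ij} = 1$ ($i \ne j$) and a
fixed one-to-one interlayer coupling of strength $\sigma$.  The healthy
organ corresponds to frequency-synchronized layers; the pathological
(septic) state is a multifrequency cluster in the parenchyma, where a group
of nodes runs at a deviating collective frequency.

Model assumptions worth keeping in mind:

* all oscillators are identical ($\omega^1 = \omega^2$, set to 0 in a
  co-rotating frame by default), so any frequency splitting is emergent,
  not imposed;
* adaptation is slow relative to the phase dynamics
  ($\epsilon^1 \ll \epsilon^2 \ll 1$), giving slow–fast–faster timescales:
  parenchymal cytokine weights (default $\epsilon^1 = 0.03$) react more
  slowly than immune weights ($\epsilon^2 = 0.3$);
* phase lags ($\alpha^{11} = \alpha^{22} = -0.28\pi$ by default,
  interlayer lags 0) stand in for interaction delays.

The *age parameter* $\beta$ is the phase lag of the adaptation rule.  At
$\beta = \pi/2$ adaptation is Hebbian — links between in-phase nodes are
maximally reinforced, which favours the healthy synchronized state.  Larger
$\beta$ mimics the physiological sum burden of age, inflammaging and
comorbidity; it shifts the maximal reinforcement away from synchrony and
makes pathological clustering accessible.

## Parameters

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `N` | oscillators per layer | 200 | – |
| `alpha11`, `alpha22` | intralayer phase lags | $-0.28\pi$ | rad |
| `alpha12`, `alpha21` | interlayer phase lags | 0 | rad |
| `beta` | age parameter (adaptation lag) | $0.5\pi$ | rad |
| `eps1`, `eps2` | adaptation rates | 0.03, 0.3 | 1/time |
| `sigma` | interlayer coupling | 1 | – |
| `C` | immune activation cluster size | 40 | nodes |
| `t_end` | horizon | 2000 | time |
| `window` | measure window $T$ | 1000 | time |

The defaults are the reference simulation conditions used throughout the
regime maps.  Time is in units of the phase dynamics; locked states drift
at $O(1)$ rad/time, so the default horizon covers a few hundred rotations.

## Initial conditions: what the generator emulates

`generate_initial_state(N, C, seed)` draws the perturbed state that models
the *onset* of a systemic immune activation, not the healthy rest state:

* phases of both layers i.i.d. uniform on $[0, 2\pi)$ — maximal ignorance
  about metabolic alignment;
* parenchymal weights $\kappa^1_{ij}$ i.i.d. uniform on $[-1, 1]$ —
  unstructured baseline cytokine activity;
* immune weights $\kappa^2$ set to a deterministic two-block matrix: 1
  inside a cluster of size $C$ and inside its complement, 0 between — a
  localized infection that has organized part of the immune system.

Because the base topology is all-to-all, the placement of the $C$-block is
arbitrary; it is fixed to the first $C$ indices for reproducibility.  The
half-open phase interval and the zero weight diagonal are measure-zero /
structural choices with no dynamical effect.  Draw order (phi1, phi2,
kappa1 row-wise) is fixed so that a seed identifies a state bitwise.

What the generator does *not* emulate: graded or multi-cluster immune
activations, heterogeneous natural frequencies, or organ-specific
topologies.  Ensemble statements made by the package are therefore
statements about this idealized perturbation ensemble, and passing checks
on it do not by themselves validate the model against clinical data.

A deliberate design choice on the coupling sums: both sums run over
$j \ne i$ and weight diagonals are held at zero.  A self-link would only
add a node-independent $\sin(\alpha)$ drift, but excluding it keeps the
reduced model below exact up to the explicit $(N-1)/N$ factor.

## Measures and thresholds

All measures operate on the trailing window $[t_{end}-T,\, t_{end}]$ of a
trajectory whose phases are stored *unwrapped* (never reduced mod $2\pi$):

* **Mean phase velocity** per node: the endpoint difference
  $(\phi_j(t_{end}) - \phi_j(t_{end}-T))/T$.  This is exact for any
  trajectory, but only meaningful if sampling resolves the rotation;
  `unwrap_check()` guards against aliasing.
* **Frequency standard deviation** $\sigma_\chi$: population standard
  deviation (divisor $N$) of the node velocities about the layer mean; its
  ensemble average $s^\mu$ measures pathogenicity (layer 1) or immune
  activation (layer 2).
* **Frequency cluster**: a layer is flagged when any node deviates from
  the layer mean by more than $\delta = 0.01$ rad/time.  The strict
  inequality of the definition needs a numerical band; $\delta$ is chosen
  well above finite-window noise ($\sim 2\pi/T \approx 0.006$ at
  $T = 1000$) and well below observed cluster splittings ($\gtrsim 0.1$
  rad/time).  Nodes are grouped by single-linkage on sorted velocities
  with gap $> \delta$; the grouping algorithm is a package choice, as only
  the flag itself is canonical.
* **Second-moment Kuramoto–Daido order parameter**
  $R_2 = |N^{-1}\sum_j e^{2i\phi_j}|$, time-averaged over the window.
  $R_2 = 1$ marks antipodal states (in-phase or anti-phase) and $R_2 = 0$
  splay states.  A frequency-synchronized layer with time-averaged
  $R_2 < 0.05$ is classified splay; the exact-zero definition again needs
  a band.
* **Interlayer locking**: all per-node differences
  $\phi^1_i - \phi^2_i$ must have standard deviation $< 0.01$ rad over
  the window; offsets are window means mod $2\pi$.

`classify_state()` maps these to four labels with a fixed precedence:
parenchymal cluster → pathological; immune-only cluster → activated immune
with resilient parenchyma; synchronized with low parenchymal $R_2$ →
splay-vulnerable; otherwise in-phase healthy.  The precedence makes the
classification total.

## Numerical integration

The state vector packs both phase vectors and both full weight matrices
(column-major, structurally zero diagonals) into one flat vector of length
$2N + 2N^2$.  The right-hand side is evaluated in compiled C; pairwise
sines are expanded through per-node sines/cosines so an evaluation costs
$O(N^2)$ multiplications rather than $O(N^2)$ trigonometric calls.

The system is smooth, non-stiff, and slow–fast rather than stiff, so an
explicit adaptive method is appropriate.  The default is the
adaptive-order Adams multistep method (via `deSolve`, `rtol = 1e-6`,
`atol = 1e-8`), which needs several-fold fewer right-hand-side
evaluations per unit time than embedded Runge–Kutta pairs at equal
tolerance on this system; an RK 4(5) pair (`method = "ode45"`) is kept as
a cross-check and the two agree on reference runs.  Integration proceeds
in chunks of a few hundred samples so that the dense $O(N^2)$ solver
output never accumulates; the trajectory object stores the full phase
history but only the final weight matrices (optionally snapshots at a
stride), since the measures need phases over a window and weights at the
end.

Two numerical caveats are made explicit by the test suite rather than
hidden:

* The model has a neutral direction (global rotation), so absolute phases
  accumulate a common integration error of order $10^{-4}$–$10^{-3}$ rad
  over hundreds of rotations at the default tolerance.  Convergence under
  tolerance halving is therefore asserted on rotation-invariant structure
  (intralayer phase shape, interlayer lag, derived measures), which is
  what every analysis in the package consumes.
* Trajectories from random initial conditions pass through transiently
  chaotic regions; two runs at different tolerances may end at slightly
  different absolute phases while agreeing on every measure.

Degenerate inputs are rejected with structured errors (dimension
mismatches name the offending field; `C` outside $1 < C < N$; windows
longer than the trajectory; integration failures report the last good
time, NaN states abort with a diagnostic).

## The analytic reduced model

For the fully synchronized state the adaptation equation can be solved by
an exponential kernel: $\kappa(t) = -\epsilon\int_0^\infty e^{-\epsilon s}
\sin(\Delta\phi(t-s) - \beta)\,ds$ (`kappa_kernel()`, quadrature truncated
where the kernel falls below $10^{-10}$).  With all intralayer phase
differences zero the weights integrate out to $\sin\beta$ and the duplex
collapses to two scalar phases (`reduced_sync_rhs()`).  Equating the layer
frequencies yields the locked interlayer lag
$\sin(\phi^1 - \phi^2) = -\sin\alpha^0/(2\sigma)$ (`sync_phase_lag()`),
hence the existence bound $\sigma > |\sin\alpha^0|/2$
(`sync_existence_bound()`, $\approx 0.385$ at $\alpha^0 = -0.28\pi$) and
the common drift $-\sin\alpha^0(\sin\beta + 1/2)$
(`sync_common_frequency()`).

The principal arcsin branch is returned: the companion solution
$\pi - \Delta$ is the unstable lock (the linearization about the locked
lag has rate $-2\sigma\cos\Delta$), and stability is confirmed
numerically in the tests rather than claimed analytically.  Full
simulations reproduce the analytic lag after an explicit $(N-1)/N$
finite-size correction, which arises because the $j \ne i$ sums average
$N-1$ terms against the $1/N$ prefactor.

No closed-form correction for coexisting frequency-cluster states is
implemented: the required cluster correction terms have no explicit
formulas, only a temporal-averaging sketch, and are out of scope.

## Ensembles, sweeps, and problem sizes

The system is strongly multistable: for fixed parameters, different random
initial conditions reach different asymptotic states (as different
patients with the same risk profile have different outcomes).  All regime
statements are therefore ensemble statements.  `sweep_grid()` reuses the
identical member seed list at every grid point, so cell-to-cell
differences are attributable to parameters alone, aggregates are
independent of execution order, and any artifact is reproducible from
(master seed, grid) alone.  The frequency-cluster ratio $f^\mu$ — the
fraction of members whose layer holds a cluster — is the probability proxy
for pathology.  One-dimensional curves can be smoothed with a trailing
4-point moving average (edges truncated); trailing alignment is a package
choice.  A `C` axis is expressed as the fraction $C/N$.

The package's working scale for ensemble studies is $N = 50$, ensembles
of 10 members, horizon 1000 with window 500, and the full reference scale
($N = 200$, 50 members, horizon 2000, window 1000) is available through
the same interfaces by changing the arguments.  All-to-all coupling makes
the regime boundaries only weakly size-dependent, and the reduced-scale
maps reproduce the qualitative regime structure: decoupled layers below
the existence bound, a pathology threshold in $\beta$ that rises with
$\sigma$, and saturation of that threshold at large $\sigma$.

One genuine feature of the model sharpened by the scaled-down ensembles:
at high age parameter the parenchyma is multistable *even when decoupled
from the immune layer* — a minority of random initial conditions reach
solitary states in which a single node runs at a deviating frequency
(offsets of 0.4–0.8 rad/time), so the parenchymal cluster ratio need not
vanish below the critical interlayer coupling.  A first-positive-$f^1$
reading of the critical coupling can therefore trigger on this fringe
rather than on the regime transition proper; the sweeps in the acceptance
material report it as computed, and the corresponding check documents the
discrepancy explicitly instead of masking it.

## Known limitations

* One-variable phase oscillators abstract all cellular metabolism; no
  organ-specific structure, no distinct immune cell types, no explicit
  cytokine concentrations.
* Phase lags are a proxy for delays, not true delay differential
  equations.
* The classification thresholds ($\delta$, splay band, locking tolerance)
  are numerical conventions for the strict definitions; results near a
  regime boundary can be sensitive to them at small window lengths.
* Trajectory persistence is in-memory / RDS; regime maps export to tidy
  CSV and measures to JSON.
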