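---
title: "Deciding between memory and naive responses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding between memory and naive responses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memstrat)
```

## The model

`memstrat` treats immune memory as a decision-theoretic resource. Antigens
live in a one-dimensional shape space; a receptor whose cognate antigen sits
at distance $d$ from the infecting antigen binds it with affinity

$$E_{\alpha,\theta}(d) = E_{\max}\,\frac{\alpha}{\alpha_{\max}}
  \exp\!\left[-(\alpha d)^\theta\right].$$

The specificity $\alpha$ controls an affinity/cross-reactivity tradeoff: peak
affinity grows with $\alpha$ while the recognition width shrinks as
$1/\alpha$. The shape factor $\theta$ interpolates between a flat profile
($\theta = 0$, no tradeoff), a double exponential ($\theta = 1$), a Gaussian
($\theta = 2$, the default used throughout), and top-hat-like profiles at
large $\theta$. The proportionality constant is fixed so the most specific
receptor ($\alpha = \alpha_{\max}$) binds its cognate antigen with affinity
$E_{\max}$; this is what normalizes lifetime net utilities to 1 for a
conserved antigen at zero cost, and it is the convention every scaled
quantity in the package relies on.

Upon re-infection, the stored memory receptor may recognize the antigen
during a deliberation window before a novel (naive) response is initiated.
With binding at a rate proportional to affinity, the naive branch is taken
with probability $p_0 = e^{-E(d)\,\beta}$, where $\beta$ — the *deliberation
factor* — is the pathogen load accumulated over the deliberation time. The
same $\beta$ plays the role of the information-processing efficacy in a
maximum-entropy decision rule: the sigmoidal decision distribution
$q_{\mathrm{mem}} \propto e^{\beta U_{\mathrm{mem}}}$ reproduces the kinetic
recognition law exactly when the utility gap is
$\Delta U = \log(e^{E\beta} - 1)/\beta$; `decision_distribution()` and
`utility_gap_from_recognition()` implement this consistency and the test
suite verifies it to $10^{-10}$. Deliberation is not free: the naive branch
carries a cost $-E_{\max}\hat\Omega(\hat\beta)$ with
$\hat\Omega = 0,\ \hat\Omega_0\hat\beta,\ \hat\Omega_0\hat\beta^2$ for the
none/linear/quadratic cost models, and the kinetic origin of the window is
exposed by `deliberation_time()`, $\tau = \tau_0 + t_{1/2}\ln b/\ln 2$,
about 1.5–5 days across the measured ranges of its inputs.

Engaging an off-centered memory is kinetically favorable but energetically
sub-optimal. The package prices this as a dissipation: the expected binding
profile after an encounter (the recognition-probability-weighted mixture of
the kept-memory profile and a freshly stored antigen-centered profile) is
compared with the optimal antigen-centered profile through a
Kullback–Leibler divergence, in nats, per unit deliberation:

$$K_{\mathrm{diss}}(d) = \frac{1}{\beta}
  D_{KL}\!\left(\bar E \,\Vert\, E_{\mathrm{antigen}}\right).$$

The per-encounter *net utility* is
$U_{\mathrm{net}} = \langle U\rangle - K_{\mathrm{diss}}$ with
$\langle U\rangle = U_{\mathrm{mem}}p_{\mathrm{mem}} +
U_{\mathrm{naive}}p_0$, and strategies $(\alpha, \beta)$ are ranked by the
total net utility accumulated over a lifetime of encounters.

## Synthetic pathogen evolution

The only data the pipeline consumes are antigenic-distance trajectories
generated by `pathogen_process()`. A lineage drifts so that $k$ rounds after
the current memory was stored, the distance is drawn from
$\mathcal N(\delta k,\ 0.05\,\delta k)$, truncated at zero by redrawing;
$\delta$ is the mean divergence per infection round and the relative spread
0.05 models how a trajectory samples the shape space around the stored
antigen. The scaled divergence $\hat\delta = \delta\,\alpha_{\max}$ measures
drift against the minimal cross-reactive range. The drift clock resets
whenever a naive response re-centers memory on the current antigen. The
default linear growth of the mean distance can be switched to
$\delta\sqrt{k}$ (`drift_scaling = "sqrt"`), the root-mean-square
displacement of a pure diffusion; the two coincide at $k = 1$ and the
default follows the linear rule.

What this generator does *not* emulate: explicit multi-dimensional antigenic
coordinates, within-host dynamics, co-circulating lineages, or
immune-driven (rather than diffusive) escape. Tests passing on these
trajectories say the decision theory is implemented correctly under
diffusive drift with small relative spread; they do not validate the model
against real antigenic maps.

## Numerical choices

**Profiles and KL grids.** Binding profiles are discretized on uniform
grids extending 8 cross-reactive ranges ($8/\alpha$) beyond *each* profile
center, with 801 points, and normalized to unit sum. Extending beyond each
center (rather than a fixed window about the midpoint) keeps both profiles
covered at any separation. For $\theta \in \{1, 2\}$ doubling the grid
resolution changes any dissipation value by less than $10^{-4}$ nats, and
the saturated $\theta = 2$ limit reproduces the closed-form Gaussian KL
$(\alpha d)^2/\beta$ to 1%.

**Dissipation cache.** $K_{\mathrm{diss}}\beta$ depends only on the scaled
separation $s = \alpha d$ and on $\lambda = \beta E(0)$, so the optimizers
tabulate one KL curve per $(\alpha, \beta)$ grid point on 2048 $s$-points
(built by shared C++ profile matrices) and interpolate; the exported
`dissipation_interpolant()` agrees with direct evaluation to $10^{-6}$.
Cached tables are memoized per kernel family and strategy grid, so a
divergence scan pays the construction cost once. Beyond the tabulated range
the recognition probability is below $\sim 10^{-15}$ and the dissipation is
treated as zero.

**Lifetime simulation.** Round 1 is a naive response that seeds memory and
is not scored: the utilities compare memory against naive responses to
re-infections, and scoring the memoryless primary round would only add a
constant. One memory slot is kept; storage overwrites on naive responses
and memory responses leave it unchanged, with no intrinsic expiry. Grid
sweeps (default $50\times50$ over
$[0,\alpha_{\max}]\times[0,\beta_{\max}]$, 200 lifetimes of 60 encounters)
use common random numbers — identical drift innovations and decision draws
across grid points — so that surface differences reflect strategy, not
noise; argmax ties break toward the cheaper strategy (smallest $\beta$,
then smallest $\alpha$). These desk-scale budgets locate the argmax to grid
resolution; budgets are configurable for larger studies.

**Mixture strategies.** A repertoire of $N_m$ specificities recognizes via
the escape product $1 - e^{-\tilde\beta \bar E}$ with $\bar E$ the mean slot
affinity and $\tilde\beta = N_m\beta$ the effective deliberation. The
package fixes the *effective* deliberation when comparing mixtures
($\tilde\beta = 0.2\,\beta_{\max} = 2$ in the shipped analyses): it is the
extensive quantity comparable across repertoire sizes, and only under this
reading do specific+cross-reactive mixtures outperform pure-specific ones,
which is the phenomenon of interest. Which slot answers an infection is
drawn with probability proportional to its affinity. Per-round accounting
mirrors the single-memory case with the realized responder's profile as the
memory profile and the mixture recognition weight in the expected profile;
the model does not uniquely define dissipation when several memories
coexist, and this single-responder generalization is isolated behind one
function so alternatives can be swapped in.

**Mixture optimization.** Specificity vectors ascend the *lifetime-summed*
net utility (the optimization target is a sum over an organism's
infections; per-encounter gradients are of order $10^{-3}$ per specificity
unit and would not transport mass across $[0, \alpha_{\max}]$ in any
reasonable number of steps). Gradients are estimated per step from 30
Gaussian perturbations (SD $0.05\,\alpha_{\max}$) of the vector by a
least-squares fit with an intercept, probes sharing random numbers with the
base evaluation; steps are $\epsilon = 0.1$ times the estimated gradient,
components clipped to $[0, \alpha_{\max}]$. Desk-scale defaults (20 slots,
50 antigen lineages of 40 encounters, 300 steps, 20 restarts) produce the
pooled bimodal specificity distribution in a few minutes; the histogram
uses 0.05-wide bins and reports the highest-mass bins below and above
$\hat\alpha = 0.75$ as the two modes.

## Design choices made where the design was open

- The kernel's proportionality constant (peak $E_{\max}$ at
  $\alpha = \alpha_{\max}$) is forced by requiring unit net utility for
  conserved antigens at zero cost.
- $0^0 := 1$ in the kernel exponent so $\theta = 0$ is exactly flat.
- Dissipation at $\beta = 0$ is defined as 0 by continuity (no memory
  engagement means the expected profile already is the optimal one).
- The dissipation reference profile shares the strategy's own
  $(\alpha, \theta)$; it is the profile fresh memory would have, not the
  best profile any receptor could have.
- Negative drift draws are redrawn rather than clipped, preserving the
  stated relative spread (at 0.05 relative SD a negative draw is a
  $20\sigma$ event, so this is a formality).
- The per-slot deliberation of a mixture is $\tilde\beta/N_m$ exactly.

## Known limitations

- The location of the transition from specific to cross-reactive optimal
  memory is sensitive to the dissipation accounting. With the
  per-unit-deliberation KL used here, the single-memory optimum stays
  within 5% of $\alpha_{\max}$ up to $\hat\delta \approx 0.5$ under a
  linear cost of amplitude 0.1; accounting variants that price dissipation
  more heavily (for instance, saturating the expected-profile weight) move
  this boundary down to $\hat\delta \approx 0.2$–0.25 while changing the
  deliberation trend, so the boundary should be read as
  convention-dependent rather than a sharp model prediction.
- For very short lifetimes the optimal deliberation sits on a broad, flat
  ridge (at $\hat\delta = 0.35$, lifetimes of two encounters give
  $\hat\beta^* \approx 0.55$ with the total utility within $10^{-3}$ of the
  ridge over $\hat\beta \in [0.49, 0.6]$), so small accounting differences
  move $\hat\beta^*$ appreciably without changing the utility attained.
- The mixture objective is stochastic and its landscape is nearly flat in
  the location of the cross-reactive mode over
  $\hat\alpha \approx 0.5$–0.7; the mode's position is therefore less
  reproducible than its existence.
- Memory re-diversification (secondary affinity maturation of recalled
  memory) is outside the model: memory profiles are fixed at storage.

## A worked example

```{r example, eval = FALSE}
fam <- kernel_family(theta = 2, alpha_max = 4, e_max = 1)
cost <- deliberation_cost("linear", 0.1)

# one host lifetime against a moderately evolving pathogen
set.seed(1)
simulate_lifetime(mem_strategy(alpha = 3, beta = 4), fam,
                  pathogen_process(0.3 / 4), cost, L = 30)

# optimal strategy at small divergence
set.seed(2)
optimize_strategy(fam, pathogen_process(0.05 / 4), cost)
```

The `analysis/` directory holds the numbered drivers that reproduce the
package's headline analyses (kinetics, phase diagram, mixture bimodality,
lifetime dependence) and write their tables under `results/`.
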