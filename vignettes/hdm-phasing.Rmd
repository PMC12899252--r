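---
title: "Direct phasing with hybrid difference-map algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct phasing with hybrid difference-map algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hdmphase)
```

## The phase problem and iterative projection

An X-ray diffraction experiment on a protein crystal measures only structure
factor amplitudes $|F_{obs}(h)|$; the phases $\varphi(h)$ needed to compute
the electron density $\rho(r)$ are lost. Direct (ab initio) phasing recovers
them from two sources of prior knowledge, each expressed as a projection
operator onto a constraint set:

* $P_A$, the **real-space projector**: the solvent region of the cell is
  featureless (density set to exactly zero here) and the protein region's
  density histogram at a given resolution is essentially universal across
  proteins, so the protein voxels are rank-order remapped onto a reference
  quantile curve (histogram matching). The voxel of rank $r$ among $m$
  protein voxels receives the reference quantile at level $(r-0.5)/m$, ties
  broken by voxel index, which makes $P_A$ exactly idempotent.
* $P_B$, the **Fourier-space projector**: the calculated amplitudes are
  replaced by the observed ones, $|F| \leftarrow w(h)\,|F_{obs}(h)|/\lambda$
  with $\lambda = \sum w|F_{obs}| / \sum |F_{cal}|$ over the work set, while
  calculated phases are retained. Reflections held out (free set), missing,
  noisy ($\sigma_F > 2|F_{obs}|$) or at very low resolution (beyond 15 Å by
  default) are filled from calculated values,
  $|F_{miss}| = (\sum|F_{obs}|/\sum|F_{cal}|)\,|F_{cal}|$ on the observed
  scale — on the map scale they simply keep their calculated amplitude,
  which is the same statement and, importantly, stays neutral under
  resolution weighting (a weighted fill ratio feeds back on itself and
  diverges). $F(000)$ and
  Fourier coefficients beyond the measured resolution sphere are unmeasured
  and pass through unchanged — the real-space constraints determine them.
  With unit weights $P_B$ is idempotent.

A solution is a density satisfying both constraints simultaneously. Because
the constraint sets are non-convex, plain alternation (error reduction,
$P_A P_B$) stagnates in local minima; practical algorithms add relaxation or
negative feedback.

## The update-rule family

Writing $\rho_n$ for the iterate and $S$ for the current protein region, the
package implements eight update rules sharing one $P_A$ and one $P_B$
implementation:

* **DiffMap**: $\rho_{n+1} = \rho_n + \beta_0(\rho_A - \rho_B)$ with the two
  candidate solutions
  $\rho_A = P_A[(1+\beta_0^{-1})P_B\rho - \beta_0^{-1}\rho]$ and
  $\rho_B = P_B[(1-\beta_0^{-1})P_A\rho + \beta_0^{-1}\rho]$. The $P_A$
  bracket of $\rho_A$ is expanded over the cached projections
  ($(1+\beta_0^{-1})P_AP_B\rho - \beta_0^{-1}P_A\rho$) so that at
  $\beta_0 = 1$ the update reduces exactly to the global form
  $\rho + (2P_AP_B - P_A - P_B)\rho$; the literal composition through the
  nonlinear histogram-matching operator does not, and is available via
  `expand_pa = FALSE`.
* **HIO**: $\rho_{n+1} = P_AP_B\rho_n$ in $S$;
  $\rho_n - \gamma P_B\rho_n$ outside (negative feedback in the solvent).
* **Hybrid formulas f1–f6**: the solvent row is always HIO's feedback
  $\rho - \gamma P_B\rho$; the protein row combines $P_AP_B\rho$ with a
  DiffMap-style relaxation term —
  f1/f2: $+\,\beta(2P_AP_B - P_A - P_B)\rho$;
  f3/f4: $+\,\beta(P_AP_B - P_A)\rho$;
  f5/f6: $+\,\beta(P_AP_B - P_B)\rho$.
  f1/f3/f5 fix $\beta = \gamma = 1$; f2/f4/f6 expose them (recommended range
  0.5–1.0; 0.75 is the default used throughout the package's studies).

Each step evaluates $P_B$ once and $P_A$ at most twice, reusing
$P_AP_B\rho$ and $P_A\rho$ for both the update and the convergence
diagnostics.

## Envelope reconstruction

The protein region is not known a priori. Every 10 iterations (configurable)
the density **estimate** — the amplitude-projected map $P_B\rho$ — is
convolved with a periodic Gaussian whose width ramps linearly from 4.0 Å to
2.5 Å over the pre-finishing iterations, and the top $(1 - f_{solv})$
fraction of smoothed voxels becomes the protein mask. Using the estimate
rather than the raw iterate matters: the iterate's solvent region carries the
accumulated negative-feedback search signal, which would drown the envelope
contrast entirely. The smoothing is implemented in reciprocal space
(multiplication by $e^{-2\pi^2\sigma^2 s^2}$), so periodicity is exact, and
the threshold is an order statistic with deterministic index tie-breaks.

Because solvent flattening plus an unconstrained $F(000)$ put the map on a
relative scale with a strictly positive protein mean, the smoothed map has
genuine protein/solvent contrast. (Pinning $F(000) = 0$ would force the
protein-region mean to zero and destroy that contrast; this is why the
package leaves $F(000)$ free.)

## Phasing strategies

* **Conventional**: all work amplitudes constrained from iteration 1.
* **Resolution-weighted**: amplitudes are multiplied by the Gaussian
  low-pass $w(h) = e^{-2(\pi\sigma_w s_h)^2}$ with $\sigma_w$ ramped
  linearly from 0.8 Å to 0 over the first 30% of the run (the ramp fraction
  mirrors a few-thousand-iteration ramp in a 10,000-iteration run); the
  molecular envelope is located before fine detail enters. With
  $\sigma_w = 0$ this is bit-identical to the conventional scheme.
* **Genetic evolution**: a population (default 100; the package's toy
  studies use 20) of otherwise independent trials exchanges information
  every `cadence` (100) iterations. Individual quality is the dynamic
  fitness $f_i = (R_{thres} - R_{work,i})/(R_{thres} - R_{min})$ clamped to
  $[0,1]$, with $R_{thres} = R_{avg} + (R_{avg} - R_{min})$. Parents are
  drawn by roulette; all chromosomes are first aligned to the fittest
  individual by protein-mask cross-correlation over the allowed origin
  shifts (and inversion where the hand is ambiguous); crossover swaps five
  random periodic boxes covering 50% ± 2% of the grid; mutation replaces
  each voxel with Uniform[0,1] with probability 0.01. Near-duplicates of a
  fitter individual (map correlation > 0.98) have their fitness halved;
  the fitness elite (5) and all converged individuals are copied unchanged.
  Replacement is steady-state: each generation only the weaker half of the
  mature non-elite slots is refreshed, and offspring are immune for
  `offspring_grace` (4) generations — a 50/50 chimera of a converged and an
  unconverged parent needs roughly 370–390 iterations to lock in (measured
  directly on the toy crystal), so purely generational replacement would
  recycle offspring before they can mature. Once every individual satisfies
  the convergence verdict the evolution terminates early and all individuals
  run the finishing protocol.

## Metrics and the convergence verdict

Per iteration the engine records $R_{work}$ and $R_{free}$
($\sum||F_{obs}| - \lambda|F_{cal}||/\sum|F_{obs}|$, $\lambda$ always from
the work set), the mean phase error
$\Delta\varphi = \langle \arccos\cos(\varphi_{true} - \varphi_{cal})\rangle$
over work reflections when true phases are supplied (≈90° for random
phases), the envelope IoU against a known true mask, and the regional
density deviations — the mean absolute value of the update rule's own
protein-region residual term over $S$ and of $P_B\rho$ over the solvent.
Both deviations sit high during the search phase and collapse at
convergence, giving a truth-free signal.

The convergence verdict (the literature gives no numeric rule) is: there is
a pre-finishing iteration $j$ at which $R_{free} < 0.35$ has been sustained
for 200 iterations and both density deviations are below 50% of their
trailing-1000-iteration medians. Evaluating the rule *at* the transition
(rather than at the end of the run) matters for runs that converge early,
since afterwards the trailing medians are themselves small. When true phases
are known, a trial is additionally scored a success if its final
origin/hand-aligned phase error is below 30°.

Reported phase errors of solved maps are computed after alignment: the map
is overlaid on the truth by FFT cross-correlation over the allowed origin
shifts (all translations in P1) and, where the space group leaves the hand
ambiguous, inversion. An ab initio solution's origin and hand are arbitrary,
so unaligned errors of perfect solutions would sit at 90°.

## Finishing protocol

During the last `n_finish` (500) iterations the update rule is linearly
ramped off ($\beta$, $\gamma$, and DiffMap's step factor scaled by
$u = $ remaining/`n_finish`) and each iterate is re-projected through plain
$P_A P_B$ — solvent flattening plus amplitude projection. The envelope is
frozen at its last pre-finishing update. This polishes the density and
typically removes 5–20° of phase error.

## The synthetic toy crystal

The generator emulates a small protein crystal with exact ground truth:

* 30 Gaussian pseudo-atoms (widths 0.8–1.2 Å, random weights), centres
  drawn in a molecular ball whose volume matches the protein fraction —
  a protein is one compact connected molecule;
* an **envelope pedestal**: a smooth plateau (height 1.2× the mean blob
  density, cosine falloff over 3 Å) filling the ball, because a real
  protein fills its envelope with near-uniform density — isolated blobs
  alone leave nothing for solvent-content thresholding to find;
* blob density synthesized in reciprocal space (exact periodicity;
  Nyquist-plane coefficients zeroed so even grids stay exactly symmetric),
  pedestal added analytically in real space; for space groups beyond P1 the
  molecule sits at a general position and is expanded over the symmetry
  operations, and the mask is closed under the group action;
* the true mask is iterated to a **fixed point of the envelope operator**
  (threshold of the 2.5 Å-smoothed flattened map); without this, a
  perfectly phased run's mask disagrees with the stored truth at the
  boundary and imposes an ~18° floor on the attainable phase error;
* the solvent region is then zeroed exactly, observed amplitudes are the
  exact structure-factor moduli of this map, and the reference histogram is
  the full sorted protein-region value set.

The truth is therefore an exact fixed point of all eight update rules, which
the test suite asserts to 10⁻⁸. What the toy does **not** emulate: measurement
noise (available separately via `add_noise()`), bulk-solvent smearing of
low-resolution amplitudes, atomic B-factors, anisotropy, and the sheer size
of real data sets — so passing toy benchmarks demonstrates the machinery and
the relative behaviour of algorithms and strategies, not absolute success
rates on deposited data.

## Numerical choices

* Grid: the smallest even 7-smooth dimensions at or below `d_min/2` spacing
  such that no reflection inside the resolution sphere aliases onto another.
  Exact synthetic amplitudes are strictly band-limited, so Nyquist sampling
  is lossless for them, and run time scales with the voxel count. The GA
  chromosome lives on the same grid (~1 Å spacing for the default toy).
* All randomness flows from one master seed through a counter-based
  splitting rule (`split_seed(seed, trial, purpose)`), so any trial of any
  study is reproducible in isolation; traces are bit-identical across
  repeated runs.
* Degenerate inputs: an all-zero map has undefined phases and raises an
  error in $P_B$; an individual zero-amplitude coefficient takes phase 0 by
  convention; a trial whose density diverges to non-finite values is marked
  `failed` rather than raising.
* Scaled-down study sizes used by the automated checks: 30 Å cubic P1 cell,
  70% solvent, 2 Å data (~7100 reflections, 32³ grid), 2000-iteration runs
  with 500 finishing iterations, 10–20 trials per configuration, GA
  population 20 at cadence 100, and 1200-iteration runs for the parameter
  sensitivity screens (gross success/failure is established well before
  2000 iterations there).

## Known limitations

* The parameter-free first hybrid formula (f1, $\beta=\gamma=1$) is locally
  stable at the toy's exact solution but its global search orbits without
  entering the basin on this exact-amplitude synthetic data class; the
  measured stability edge is $\beta \approx 0.85$–0.9 ($\gamma = 1$ is
  unproblematic). The parameterized f2 at $\beta=\gamma=0.75$ solves the
  same toy from random starts in a majority of trials. This mirrors the
  general observation that overly strong feedback destroys convergence,
  with the edge's location depending on the data; on real data with noise,
  B-factors and bulk solvent the edge can sit above 1.
* Only a small built-in space-group table (P1, P-1, P21, P212121) ships
  with the package; arbitrary groups can be supplied as explicit operator
  lists and are checked for closure.
* Map-averaging weights are uniform; no figure-of-merit weighting.
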