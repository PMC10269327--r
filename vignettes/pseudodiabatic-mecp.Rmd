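---
title: "Pseudodiabatic surrogates for minimum-energy crossing point optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudodiabatic surrogates for minimum-energy crossing point optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conikit)
```

## The model

`conikit` locates minimum-energy crossing points (MECPs) between two
electronic potential energy surfaces: conical intersections (CIs) between
states of the same spin, and crossings between states of different spin.
The obstacle in the CI case is geometric: the adiabatic energies
$E^A \ge E^B$ touch along a seam of dimension $m - 2$ and are not
differentiable there; the gap grows linearly in the two-dimensional
*branching plane* spanned by the half gradient-difference
$\mathbf{g} = (\nabla E^A - \nabla E^B)/2$ and the (difference-scaled)
nonadiabatic coupling $\mathbf{h}$, producing the familiar double cone.
Any surrogate model built directly on $E^A$, $E^B$ inherits the cusp.

The package therefore models the *diabatic* quantities of a two-state
Hamiltonian

$$ H(\mathbf q) = \begin{pmatrix} \alpha & \gamma \\ \gamma & \beta \end{pmatrix},
\qquad \tau = \tfrac{\alpha+\beta}{2},\;
\delta = \tfrac{\alpha-\beta}{2},\;
\lambda = \sqrt{\delta^2 + \gamma^2},\;
\omega = \operatorname{atan2}(\gamma, \delta), $$

with $E^A = \tau + \lambda$, $E^B = \tau - \lambda$ and the gradient
relations $\mathbf s = \nabla\tau$,
$\mathbf g = \cos\omega\,\nabla\delta + \sin\omega\,\nabla\gamma$,
$\mathbf h = -\sin\omega\,\nabla\delta + \cos\omega\,\nabla\gamma$.
$\alpha$, $\beta$, $\gamma$ are smooth through the seam, so each can be
interpolated by a smooth regressor; the cone reappears, exactly, on
diagonalization. This is a *pseudo*diabatization: no claim is made that
residual couplings vanish, only that the three surfaces reproduce the
adiabatic data. The electronic wavefunctions are never examined — only
energies, gradients and the coupling vector enter.

### Gauge fixing

The adiabatic data determine $(\delta, \gamma)$ only up to a rotation: the
mixing angle $\omega$ is not observable. To obtain *consistent* diabats
across a history of geometries, the gauge is pinned at a reference structure
(the most recent point): $\mathbf k_\delta = \mathbf g(\mathbf q^{ref})$,
$\mathbf k_\gamma = \mathbf h(\mathbf q^{ref})$, so $\omega(\mathbf q^{ref}) = 0$.
At any other geometry the plane $\{\mathbf g, \mathbf h\}$ generally differs
from the reference plane, so it is first rotated onto it by the minimal
(SVD-based) rotation: with $B_1 = \mathrm{orth}([\mathbf g\,\mathbf h])$,
$B_2 = \mathrm{orth}([\mathbf k_\delta\,\mathbf k_\gamma])$ and
$B_1^T B_2 = U \Phi V^T$, the map $B_2 V U^T B_1^T$ is an isometry on the
plane and the singular values $\phi_1, \phi_2 \in [0,1]$ are the cosines of
the principal angles. A small product $\phi_1\phi_2$ (threshold 0.1) means
the planes are nearly orthogonal and the fit is flagged
(`conditioning_ok = FALSE`, with a warning but no abort — the caller may
rebuild the gauge from a closer reference).

Two estimates of $\omega$ are then read off and combined by a circular
mean. A deliberate design choice here: the angle of $\mathbf g'$ is taken
from its *pseudoinverse coordinates* in the (generally non-orthogonal)
basis $(\mathbf k_\delta, \mathbf k_\gamma)$, not from an orthonormalized
frame. For data from an exactly linear diabatic model,
$[\mathbf g\,\mathbf h] = [\mathbf k_\delta\,\mathbf k_\gamma] R(\omega)$
and the pseudoinverse recovers $R(\omega)$ — hence $\omega$ — *exactly*
whatever the angle between the gauge vectors; an orthonormal-frame angle
would not. The $\mathbf h'$ estimate is shifted by $-\pi/2$ so both
estimates agree (and vanish) in the reference gauge. Since the backend's
coupling vector carries an arbitrary sign (wavefunction phase), $\mathbf h$
is replaced by $-\mathbf h$ whenever the two angle estimates disagree by
more than $\pi/2$ on the circle; the flip is recorded, and
`diabatize_history()` additionally canonicalizes the sign of
$\mathbf k_\gamma$ (largest-magnitude component positive) so that the
resulting surfaces are invariant under *any* per-point phase choice,
including at the reference itself.

Degeneracies: $\lambda < 10^{-9}$ hartree is treated as exact degeneracy in
the diabatic-to-adiabatic direction, where $\omega = \operatorname{atan2}(0,0)$
would be undefined; the $\omega \to 0$ limit is returned with a flag. The
diabatization direction needs no such tolerance — there $\omega$ comes from
the gradients, which stay finite at the seam. Antipodal inputs to the
circular mean (arc distance exactly $\pi$) break the tie deterministically
as $x + \pi/2$; the optimizer only meets this in pathological gauges.

## The surrogate

Each diabatic quantity is fitted by gradient-enhanced Kriging: a Gaussian
process conditioned on $n$ values *and* $n m$ gradient components, giving a
data vector of length $n(m+1)$ (per point: energy first, then the $m$
gradient components, points in history order). The kernel is Matern-5/2,

$$ f(d) = \left(1 + \sqrt5\,d + \tfrac{5}{3} d^2\right) e^{-\sqrt5 d},
\qquad d^2 = \sum_k \left(\frac{q_k - q_k'}{l_k}\right)^2, $$

the smoothest member of the Matern family whose second derivatives remain
well defined at $d = 0$, which is exactly what gradient data require. All
first and mixed second derivatives are analytic; the apparent $\sqrt{\cdot}$
singularity cancels.

Choices a user can tune, with defaults and reasons:

* **Characteristic lengths** `lengths` (bohr): calibrated from a diagonal
  approximate Hessian as $l_k = \sqrt{5\,\mu_{off} / (3 H_{kk})}$, so that a
  *single-point* surface has exactly that curvature at its data point (the
  analytic one-point curvature is $\mu_{off}\,5/(3 l_k^2)$, independent of
  the stored gradient because the kernel's odd derivatives vanish at the
  origin). Entries below 0.025 hartree/bohr$^2$ are floored — lengths must
  stay positive, and a near-flat mode should not produce an effectively
  infinite length. One set of lengths is shared by all three surfaces.
* **Baselines** $\mu$: constant trends, set per energy surface to
  `mu_offset` = 10 hartree above that surface's data maximum, and to 0 for
  $\gamma$ (which oscillates around zero by construction). An elevated
  baseline makes the surface bend *upward* away from the data — the safe
  default for a minimizer — and is what gives the one-point curvature
  formula its scale. Because the prediction is invariant to an overall
  kernel variance, the prior variance is fixed at 1 and only $\mu$ carries
  units.
* **Nugget**: $10^{-10}$ on the covariance diagonal (relative to unit prior
  variance), for factorization safety. Exact interpolation is then restored
  by a few steps of iterative refinement against the unregularized matrix;
  on well-conditioned problems training values and gradients are reproduced
  to $\sim 10^{-13}$. When training points cluster far below the
  characteristic lengths the covariance becomes numerically singular
  (condition number beyond $1/\varepsilon$) and *no* solver can interpolate
  to $10^{-8}$ in double precision; the package therefore enforces a
  minimum scaled separation of $10^{-8}$ (error naming the closest pair),
  drops near-duplicate geometries in favor of the newer one, and fits only
  the most recent `max_data` = 20 points — a window in the spirit of using
  the last several iterations, which also keeps the solve cheap.
* Hyperparameters are **not** tuned by maximum likelihood: lengths and
  baselines follow the prescriptions above by construction, which keeps the
  surrogate deterministic and reproducible across runs.

The predicted variance is the simple-kriging expression
$s^2(\mathbf q) = 1 - \mathbf v^T M^{-1} \mathbf v$ (clamped at 0): zero at
training points, approaching the prior far from all data. It is used only
*relatively*, to restrict steps.

## The optimizer

A macroiteration evaluates the backend once, appends the point to the
history, rebuilds the gauge from the newest point and re-diabatizes the
whole history (the cost is negligible, and the gauge stays maximally local),
fits the three surfaces, and runs microiterations on the surrogate.

Each microiteration splits the coordinates into a constrained subspace and
its orthogonal complement. In spin mode the constraint is one-dimensional:
a Newton step along $\mathbf g$ of first-order length $\lambda/\|\mathbf g\|$
drives $E^A - E^B \to 0$. In CI mode the gap is *conical*, not
differentiable, and a one-dimensional split stalls whenever the average
gradient has a component along $\mathbf h$: the restoration direction keeps
rotating inside the branching plane and the projected gradient never
vanishes. The surrogate makes the cure natural — it exposes $\delta$ and
$\gamma$ *separately*, so the constrained subspace is
$\mathrm{span}\{\nabla\delta, \nabla\gamma\}$ and the restoration is a
Gauss-Newton step driving $(\delta, \gamma) \to (0, 0)$, whose residual
norm is exactly $\lambda$. This matches the physical stationarity
condition: at an MECP the average gradient lies in the branching plane.
In the complement, the average energy is minimized by a rational-function
(RFO) step, switching to a Levenberg-style step of exactly the trust-region
length when the RFO step is too long; the Hessian of $\tau$ is obtained by
central finite differences of the surrogate's analytic gradients (step
$10^{-4}$ bohr), which is cheap and accurate since the surrogate is smooth.

Microiterations stop at surrogate stationarity, at the iteration cap, or —
the restricted-variance rule — when a step would carry the predicted
variance past `variance_limit`; the geometry is then pulled back onto the
limit surface by bisection along the step (60 halvings, landing on the
feasible side), and that candidate goes to the backend. The default limit
corresponds to a 95% half-width of $1.96\,s \le 0.3$ on the energy
surfaces, i.e. `variance_limit` $= (0.3/1.96)^2$; the rule as published
does not fix hard-wall versus step-back semantics, and bisection-to-limit
was chosen as the more conservative of the two. Stationarity on the
surrogate is declared at `micro_conv_factor` ($10^{-4}$) times the macro
thresholds: surrogate evaluations are analytic and essentially free, so the
inner problem is solved essentially exactly, and the accepted candidate's
accuracy is limited by the surrogate's fidelity rather than by the inner
loop.

Macro convergence follows common geometry-optimization practice: rms step
$\le 1.2\times10^{-3}$ bohr, rms projected gradient
$\le 3.0\times10^{-4}$ hartree/bohr, maximum components at most 1.5 times
those values, and $|E^A - E^B| \le 10^{-5}$ hartree, all with inclusive
comparisons. The threshold pair quoted in units of Eh/bohr is applied to
the *gradient*, the bohr pair to the step. The projected gradient removes
the branching-plane directions ($\mathbf g$ and $\mathbf h$; only
$\mathbf g$ in spin mode) from $\mathbf s$.

Coordinates are plain Cartesians. For atomic systems (dimensionality $3N$),
`project_rigid = TRUE` removes overall translations and rotations
(Eckart-style, an orthonormalized basis of the six rigid modes about the
centroid) from gradients, constraint Jacobians and steps, making the
optimization equivariant under rigid motion of the input; redundant
internal coordinates are deliberately out of scope. Spin-mode state labels
follow the *spin character*, not the energy ordering: $\alpha$ and $\beta$
may cross, which is what keeps them differentiable at the seam.

## What the model backends emulate — and what they do not

The shipped families are analytic stand-ins for an electronic-structure
program, built so every claim has an independent check:

* `linear_cone` — linear diabats, a single conical apex, constant
  branching plane. The apex is known in closed form.
* `quadratic_cone` — asymmetric quadratic diabats constructed around a
  chosen crossing point $\mathbf q^*$: $\delta$ and $\gamma$ vanish there
  with independent gradients, and the average-energy gradient at
  $\mathbf q^*$ is placed inside the branching plane, so $\mathbf q^*$ is
  exactly seam-stationary. Quadratic corrections (scale ~0.15 of the linear
  terms) make the linear model fail visibly a few hundredths of a bohr from
  the MECP, echoing how real surfaces deviate from local linearity.
* `spin_harmonic` — two isotropic paraboloids with $\gamma \equiv 0$; the
  constrained minimum has a closed-form Lagrange solution (minimization of
  a quadratic on the hyperplane where the paraboloids cross).
* `random_poly` — random quadratics for property tests.

Backends report $\mathbf s$, $\mathbf g$, $\mathbf h$ by diagonalizing the
model Hamiltonian, optionally flipping the sign of $\mathbf h$
pseudo-randomly per geometry (deterministically for a fixed input, as the
backend contract requires) to exercise the phase-resolution rule.
`brute_force_mecp()` is the independent oracle: a bounded grid scan
followed by penalty minimization of $\tau + c(\delta^2 + \gamma^2)$ with
$c$ increasing to $10^8$ (the squared gap is smooth even at the seam, so
L-BFGS-B applies; bounds keep the minimizer from escaping to seams outside
the scan box).

What passing on these models shows: the diabatization, gauge handling,
interpolation and constrained-step machinery are correct, and the
macroiteration counts (typically 3–6 on the shipped suite, capped at 25 in
the acceptance checks) are in the range reported for surrogate-based MECP
optimizers on small molecules. What it does not show: behavior under
electronic-structure noise, root flipping, near-degenerate third states, or
the floppy-molecule regimes where internal coordinates and Hessian-update
strategies matter. The surrogate is a local optimization tool, not a global
representation of the surfaces — it should not be used for dynamics.

## Numerical choices, summarized

* Degeneracy tolerance $10^{-9}$ hartree on $\lambda$; gauge vectors must
  subtend at least $10^{-6}$ rad; plane-conditioning threshold
  $\phi_1\phi_2 \ge 0.1$ (warn, do not abort).
* Orthonormalization is modified Gram-Schmidt with one reorthogonalization
  pass (deterministic, which the tests rely on); dependent columns are
  dropped at relative tolerance $10^{-12}$.
* Kernel data ordering: per point, energy then gradients; points in history
  order.
* Covariance solve: Cholesky with nugget escalation ($\times 10^2$,
  $\times 10^4$) before giving up and naming the closest point pair;
  iterative refinement capped at 5 sweeps with a $10^{-14}$ relative
  residual target.
* Trust radius 0.3 bohr per micro step; variance bisection 60 iterations;
  RFO/Levenberg shift found by 80 bisections.
* Problem sizes in the shipped tests and acceptance script: 2-, 3-, 6- and
  9-dimensional models, histories of up to 20 points, 10 independent
  optimization runs per acceptance pass — chosen to exercise every code
  path while each check stays numerically sharp.

## Known limitations

* Two states only; crossings with a third state are not represented.
* The gauge is local to the reference point: far from it (small
  $\phi_1\phi_2$, or angle estimates in wide disagreement) the
  pseudodiabatization may lose consistency. The optimizer mitigates this by
  re-gauging every macroiteration at the newest point.
* Ill-conditioning limits attainable interpolation accuracy when the
  history clusters far below the characteristic lengths; the data window
  and distinctness guard manage, but do not eliminate, the effect.
* The per-step trust radius is fixed rather than adaptive; the variance
  restriction is the primary step control.
* Real-backend integration (the `BackendContract`) is defined and tested
  against the contract, not against an actual quantum-chemistry program.
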