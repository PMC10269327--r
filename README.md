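# conikit

Surrogate-based optimization of minimum-energy crossing points (MECPs)
between two electronic potential energy surfaces, for computational
chemists who locate conical intersections or spin crossings and want to
spend as few electronic-structure calculations as possible doing it.

## The problem and the method

Around a conical intersection the two adiabatic surfaces `E^A >= E^B` form a
double cone: they are continuous but not differentiable at the seam, which
defeats surrogate models built on smooth interpolation. `conikit` sidesteps
the cusp by re-expressing the two states through a 2x2 diabatic Hamiltonian

    H = | alpha  gamma |        tau = (alpha + beta)/2,  delta = (alpha - beta)/2
        | gamma  beta  |        lambda = sqrt(delta^2 + gamma^2)

whose eigenvalues `E^A = tau + lambda`, `E^B = tau - lambda` reproduce the
adiabats, while `alpha`, `beta`, `gamma` themselves are smooth through the
seam. The per-geometry data produced by any quantum-chemistry backend —
energies, the average gradient `s`, the half gradient-difference
`g = (grad E^A - grad E^B)/2` and the difference-scaled nonadiabatic coupling
`h` — determine `alpha, beta, gamma` only up to a mixing angle `omega`
(and `h` only up to a sign). The package fixes the gauge against a reference
geometry (`k_delta = g(q_ref)`, `k_gamma = h(q_ref)`, so `omega(q_ref) = 0`),
rotates each point's branching plane minimally onto the reference plane via
an SVD of the subspace inner-product matrix, reads `omega` off as the
circular mean of the angles of the rotated `g` and `h`, and flips `h`
whenever the two estimates disagree by more than pi/2.

Each of the three diabatic quantities is then interpolated by
gradient-enhanced Kriging (GEK) with a Matern-5/2 kernel and analytic
first/second derivatives, so the surrogate reproduces every training energy
and gradient essentially exactly. Characteristic lengths come from a
user-supplied approximate Hessian diagonal (`l_k = sqrt(5 mu_off / 3 H_kk)`,
chosen so a one-point model has exactly that curvature); baselines sit
10 hartree above the data for the energy surfaces and at 0 for `gamma`.

The optimizer is a restricted-variance scheme: microiterations walk the
surrogate with a projected constrained step — Gauss-Newton restoration of
the degeneracy (`delta, gamma -> 0`; just `delta` for spin crossings) plus a
restricted-step rational-function minimization of `tau` in the orthogonal
complement — and stop when the surrogate's predicted variance reaches its
limit. Each macroiteration then costs exactly one backend evaluation. For
crossings between states of different spin, `gamma` is identically zero, two
surfaces suffice, and no coupling vector is needed.

Shipped analytic two-state models (`linear_cone`, `quadratic_cone`,
`spin_harmonic`, `random_poly`) stand in for an electronic-structure
program, with known diabats, seams and (closed-form or brute-force) MECPs.

## Worked example

Optimize the MECP of an asymmetric quadratic two-state model from a start
0.5 bohr away:

```r
library(conikit)
be  <- analytic_backend("quadratic_cone", seed = 2)
res <- optimize_mecp(be$backend, be$model$known_mecp + c(0.4, -0.3),
                     opt_config(mode = "ci"))
print(res)
#> <mecp_opt> converged after 3 macroiterations
#>   E_A=-77.99999458  E_B=-78.00000295  gap=8.373e-06
res$trace[, c("macro", "gap", "rms_step", "variance", "stop_reason")]
#>   macro          gap     rms_step     variance stop_reason
#> 1     1 2.253630e-02 3.668798e-01 1.129824e-03  stationary
#> 2     2 4.437568e-05 1.650581e-02 1.807960e-09  stationary
#> 3     3 8.372579e-06 2.379978e-05 5.333889e-11  stationary
```

Three backend evaluations suffice: the `gap` column is `|E^A - E^B|` in
hartree at each accepted geometry (converged when below 1e-5 together with
the step and projected-gradient thresholds), `rms_step` is the macro step in
bohr, and `variance` is the surrogate's predicted variance at the accepted
point, always below the configured limit. The independent grid + penalty
oracle agrees with the optimized geometry to 4e-6 bohr:

```r
brute_force_mecp(be$model, bounds = 1.5)   #> -0.3151177  0.2023740
res$q                                      #> -0.3151218  0.2023807
```

The same workflow runs from a shell (`inst/cli/conikit`):

```sh
conikit optimize --backend spin_harmonic --mode spin --q 0.5,0.9 --trace trace.jsonl
conikit surface-scan --backend quadratic_cone --seed 2 --radius 0.1 --out scan.csv
conikit models list
```

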