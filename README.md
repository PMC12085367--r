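# offgridspikes

Off-the-grid reconstruction of point sources from blurred, photon-limited
images, in R.

## The problem

Fluorescence microscopy images of point emitters (single molecules,
vesicles, ER exit sites) are blurred by the microscope's point spread
function (PSF) and corrupted by Poisson noise from photon counting. The
quantity of interest is not a pixel image but a small set of spikes: a
discrete measure

```
mu = sum_{i=1..N} a_i * delta_{x_i},    x_i in Omega,  a_i >= 0,
```

with *continuous* positions — no reconstruction grid. `offgridspikes`
estimates N, the positions and the amplitudes by solving the variational
problem over the space of Radon measures

```
min_mu  f_{y,b}(Phi mu) + lambda |mu|(Omega) + alpha * indicator(mu >= 0)
```

where `Phi` maps a measure to its PSF-blurred image sampled on the
acquisition grid, `|mu|(Omega) = ||a||_1` is the total-variation norm of
the measure (the sparsity-promoting penalty), and the data term is either

* the **Kullback-Leibler divergence** `f_{y,b}(w) = D_KL(w + b, y)`
  matched to Poisson counts, with a strictly positive background `b` and
  the non-negativity constraint active (`alpha = 1`), or
* the classical **squared-L2** Beurling-LASSO term
  `f_{y,b}(w) = 0.5 ||w + b - y||^2` (`alpha = 0`), the Gaussian-noise
  baseline.

Two algorithms do the work:

* **Sliding Frank-Wolfe (SFW)** — a conditional-gradient method over
  measures. Each iteration evaluates the dual certificate
  `eta(lambda, mu) = -(1/lambda) Phi* grad f(Phi mu)` (its positive part
  under the constraint), inserts a spike where the certificate exceeds 1,
  re-estimates all amplitudes under the `l1` penalty, and then slides:
  jointly refines all positions and amplitudes by local continuous
  optimisation. It stops when `||eta||_inf <= 1`, the exact optimality
  condition of the convex problem.
* **Homotopy continuation** — automatic selection of `lambda`. Starting
  from `lambda_1 = gamma ||eta(1, mu_0)||_inf`, each outer step solves the
  problem at the current `lambda` (warm-started), checks whether the
  residual `sigma_t = f_{y,b}(Phi mu_t)` has fallen below a
  noise-calibrated `sigma_target`, and otherwise rescales `lambda` so the
  current certificate has sup-norm exactly `1 + c`. The residual decreases
  and the measure's mass grows monotonically along the path.

`sigma_target` can be calibrated from a ground truth (simulations), from a
background-only region of the acquisition (the masked estimator, which
also estimates `b`), or from the Poisson discrepancy principle.

The package also ships Gaussian-PSF forward models in 1D/2D/3D, phantom
generators with pixelwise Poisson sampling, and spike-space evaluation
metrics (tolerance-radius one-to-one matching, Jaccard index, RMSE of
matched positions and amplitudes).

## Worked example

Six random spikes on [0, 1], blurred by a Gaussian PSF (`sigma = 0.07`),
constant background 0.01, pixelwise Poisson noise, reconstructed with the
KL model and homotopy-selected `lambda`:

```r
library(offgridspikes)
preset <- scenario_preset("sim1d")
gt  <- generate_ground_truth(preset, seed = 7)
y   <- simulate_acquisition(gt, preset, seed = 107)
spec   <- fidelity_spec("kl", y = y, b = preset$b)
target <- sigma_target_oracle(gt, spec, preset$psf, preset$grid)
cfg <- homotopy_preset("kl", n_expected = 6, sigma_target = target)
rec <- homotopy_solve(spec, preset$psf, preset$grid, cfg)
rec$trace[, c("t", "lambda", "sigma", "n_spikes", "cert_sup")]
#>   t       lambda        sigma n_spikes   cert_sup
#> 1 1 696.64337511 26.237925176        1  0.9999996
#> 2 2  16.99129554 13.502131268        2 22.9261978
#> 3 3   9.50111712  7.537945103        3  2.0983141
#> 4 4   0.48625191  0.462643898        4  1.6047597
#> 5 5   0.01903213  0.005236711        5  1.0076364
evaluate_spikes(gt, rec$measure, delta = 0.05)
#>   tp fp fn   jaccard      rmse_x    rmse_a
#> 1  5  0  1 0.8333333 0.009971302 0.2726014
```

The trace shows the homotopy path: `lambda` decreases until the residual
`sigma` meets the target, inserting one spike per step. Five of the six
spikes are localised to ~0.01 spatial units (a fifth of a pixel); the
missed one sits 0.046 from a brighter neighbour — closer than the 0.05
matching radius, i.e. below the resolution the protocol scores.

A thin command-line wrapper with `simulate`, `solve`, `evaluate` and
`benchmark` subcommands is installed at
`system.file("scripts/offgrid.R", package = "offgridspikes")`.

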