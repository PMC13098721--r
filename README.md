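# smfretsim

Stochastic simulation of time-resolved confocal single-molecule FRET
(smFRET) experiments, for researchers who need to know how much of an
observed "dynamic shift" is produced by the dyes themselves rather than
by the biomolecule under study.

## The problem

In smFRET, a donor and an acceptor dye report the distance `r` between
two points of a molecule through the transfer efficiency
`E = 1/((r/R0)^6 + 1)`. Burst analysis yields, per single molecule, both
an intensity-based efficiency `E_I = I_A/(I_A + I_D)` and a normalized
donor lifetime `tau = tau_DA / tau_D0`. A single static FRET state obeys
the *static line* `E = 1 - tau`; mixing of transfer rates within a burst
pushes points above it, because the mean lifetime of a rate mixture
exceeds the lifetime of the mean rate (Jensen's inequality). The signed
orthogonal distance to the line,

    Delta(E, tau) = (E + tau - 1) / sqrt(E^2 + tau^2),

is the **dynamic shift**. The dyes are not rigid: their linkers let them
translate, and their transition dipoles reorient, so the transfer hazard

    k_ET(t) = k_D * C * kappa2(t) / r(t)^6,   C = (3/2) R0^6

is time-varying *within* each excitation, making photon emission a
time-inhomogeneous Markov chain. `smfretsim` simulates this physics end
to end — Ornstein–Uhlenbeck spring and stochastic elastic-pendulum
linker models, spherical Brownian motion of the dipoles, exact
integrated-hazard sampling of transfer times, per-photon detection
losses — and quantifies the resulting dynamic-shift distributions, so
dye-induced shifts can be separated from conformational dynamics.

## Worked example

```r
library(smfretsim)
params <- physical_params()        # k_D = 0.25/ns (tau_D0 = 4 ns), R0 = 5 nm

## 200 bursts of the elastic-pendulum model with time-varying kappa^2
tab <- run_experiment("pendulum", "dynamic", n_bursts = 200,
                      params = params, seed = 1)
head(tab, 3)
#>   burst_id I_D I_A       E_I  tau_norm mean_kappa2 n_excitations n_censored excluded
#> 1        1 195 195 0.5000000 0.6135456   0.6779939          1000          0    FALSE
#> 2        2 220 152 0.4086022 0.7419682   0.6914646          1000          0    FALSE
#> 3        3 179 204 0.5326371 0.5823265   0.6414051          1000          0    FALSE

shift_distribution(tab)
#> Dynamic shift over 200 bursts: mu = 0.1795, sigma = 0.0731
```

Each row is one burst of 1,000 excitation cycles: `I_D`/`I_A` are
detected photon counts, `E_I` the intensity efficiency, `tau_norm` the
mean donor delay over `tau_D0`, and `mean_kappa2` the per-burst average
of the kappa^2 path (2/3 in expectation). The burst cloud sits well above
the static line (`E_I + tau_norm > 1`): with slowly reorienting dipoles
the orientation factor is quasi-frozen within each excitation and
resampled between excitations, and this rate mixing inflates the mean
lifetime — the dye-induced dynamic shift. The same experiment with
`kappa2_mode = "static"` (kappa^2 pinned at 2/3) gives `mu ~ 0.15`
from translational mixing alone, and the isotropic spring model gives
`mu ~ 0.07`.

Other entry points: `simulate_spring()` / `simulate_pendulum()` /
`simulate_dipole()` (raw dynamics), `sample_transfer_time()`
(inversion and thinning samplers), `two_state_sweep()` (the two-state
mixing arc), `moment_difference()` (the moment-based diagnostic),
`preset_config()` / `run_config()` (JSON-configured runs), and a CLI:

```sh
Rscript inst/scripts/smfretsim simulate --preset pendulum_dynamic \
        --bursts 200 --seed 1 --out bursts.tsv
Rscript inst/scripts/smfretsim shift --in bursts.tsv --out shift.tsv
```

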