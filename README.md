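# cspfit

NMR chemical-shift-perturbation (CSP) titration analysis with global
dissociation-constant fitting, for structural biologists quantifying
protein–ligand (e.g. protein–RNA) binding from 2D ¹H-¹⁵N HSQC spectra.
Companion modules implement the statistics used alongside such studies:
dual-luciferase reporter normalization (stem-loop polyadenylation
assays), nuclear/cytoplasmic intensity ratios, and fully seeded
synthetic-data generators with known ground truth for every stage.

## The model

Titrating unlabeled ligand into a ¹⁵N-labeled protein moves the amide
resonances of interface residues. The weighted CSP of residue *i* at
point *t* against the ligand-free reference is

    Δδ_i,t = sqrt( ( (δN_i,t − δN_free)²/25 + (δH_i,t − δH_free)² ) / 2 )

For one-site binding P + L ⇌ PL with dissociation constant K_D and
total concentrations [P]_T and [L]_T, the bound fraction is the
physical root of the mass-action quadratic

    f_b = ( (K_D + [P]_T + [L]_T) − sqrt( (K_D + [P]_T + [L]_T)² − 4 [P]_T [L]_T ) ) / (2 [P]_T)

and the fast-exchange CSP trajectory of each residue is
Δδ_i,t = Δδ_max,i · f_b(K_D, [P]_T, [L]_T,t). `fit_global()` estimates
one shared K_D together with residue-specific Δδ_max values by
Levenberg–Marquardt least squares (seeded from a profiled 1-D
minimization over log K_D), and reports a 1σ standard error from the
covariance matrix of the fit. Exchange regimes (fast / intermediate /
slow, set by k_ex = k_on[L] + k_off relative to Δω) are classified from
peak positions and intensities; only fast-exchange residues enter the
fit by default.

The pipeline is: read peak lists (Sparky `.list` or TSV) →
`track_peaks()` (assignment-anchored nearest-neighbour tracking) →
`compute_profiles()` (CSPs, saturation, regimes) → `fit_global()` →
reports (per-residue CSP table, structure-coloring map, JSON fit
report).

## Worked example

Simulate a titration with known K_D = 3.5 μM (15 fast-exchange
residues, [P]_T = 100 μM, 11 points from 0 to 200 μM, realistic
positional noise), then run the pipeline:

```r
library(cspfit)

spec <- synthetic_titration_spec(true_kd_uM = 3.5, protein_total_uM = 100,
                                 ligand_schedule_uM = seq(0, 200, length.out = 11),
                                 seed = 1)
sim <- simulate_titration(spec, fast_residue_set(spec, n = 15))

trajs    <- track_peaks(sim$series, max_step = 0.1)
profiles <- compute_profiles(trajs)
fit      <- fit_global(profiles, sim$series)
profiles
fit
```

```
csp_profiles: 15 residues x 11 points
  regimes: fast=15
  csp_max_observed: 0.1162 .. 0.1790 ppm; 13/15 saturated
Global one-site binding fit
  K_D = 3.59 uM (SE 0.239 uM, 1-sigma from covariance)
  15 residues (fast exchange), 150 residuals, rss = 0.0006055 ppm^2
  converged: TRUE; delta_max fitted
```

All 15 residues are in fast exchange; their observed endpoint CSPs run
0.12–0.18 ppm, and the global fit recovers the true dissociation
constant (3.59 ± 0.24 μM vs. 3.5 μM simulated) with the truth well
inside one standard error.

Reporter statistics on simulated triplicate wells with a true +50%
effect and 5% multiplicative noise:

```r
wells <- simulate_slap(c(control = 1, cofactor = 1.5), n = 3,
                       noise_cv = 0.05, seed = 1)
nw <- normalize_slap(wells, "control")
s_test <- slap_summary(nw$nlu[nw$condition == "cofactor"], "cofactor")
s_ctrl <- slap_summary(nw$nlu[nw$condition == "control"], "control")
s_test
stimulation_effect(s_test, s_ctrl)
wt <- welch_t_test(nw$nlu[nw$condition == "cofactor"],
                   nw$nlu[nw$condition == "control"])
sprintf("t = %.2f, df = %.2f, p = %.4f", wt$t, wt$df, wt$p)
```

```
cofactor: 1.512 +/- 0.0402 NLU (n = 3, SE)
[1] 51.15636
[1] "t = 9.61, df = 3.92, p = 0.0007"
```

The control condition averages exactly 1 normalized luciferase unit by
construction; the +50% stimulation is recovered as +51.2% and is
highly significant under the two-tailed unequal-variance t-test.

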