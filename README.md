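# subaccess

Analysis of substrate access and binding in enzyme simulations.

Many enzymes with deep binding pockets — cephalosporin acylase is the
motivating example — are rate-limited not by chemistry but by how the
substrate reaches the active site: adsorption to the protein surface,
passage through a gated pocket entrance, and competition between productive
and non-productive poses inside the pocket. All three steps leave
statistical signatures in unbiased molecular-dynamics trajectories of an
enzyme in substrate solution. `subaccess` extracts them:

* **Reaction coordinate.** The near-attack-conformation distance
  `d_NAC = sqrt((d1² + d2² + min(d3,d4)²)/3)` built from the catalytic
  serine–carbonyl distance d1 and three oxyanion-hole distances d2–d4,
  computed per frame and substrate copy under the minimum-image convention,
  with a configurable filter that discards kinetically trapped replicates.
* **Free energy profiles.** Boltzmann inversion
  `ΔG(i)/kT = −ln(p(i)/N_ref(i))` of binned d_NAC populations against the
  analytic spherical-shell reference
  `N_ref(i) = (4/3)π((a_i+δb)³ − a_i³)·c·N_A`, with the equilibrated bulk
  concentration `c` fitted from far-field bins (> 60 Å) so the profile is
  zero in bulk by construction.
* **Surface binding.** Geometric bound-state counting (substrate centre of
  mass within 5 Å of any protein atom within 25 Å of the catalytic serine
  oxygen), replicate averaging with error propagation, and nonlinear
  fitting of the Langmuir isotherm `bound(c) = bmax·c/(K + c)` with
  broom-style `tidy()`/`glance()`/`autoplot()` methods.
* **Pose analysis.** Conformer extraction in d_NAC windows, Kabsch
  superposition on protein Cα atoms, all-atom RMSD gromos clustering, and
  per-residue contact-frequency profiles that identify gatekeeper and trap
  residues.
* **Synthetic ground truth.** Seeded generators — Metropolis Monte Carlo in
  a known radial potential, binomial site-occupancy series, planted
  conformer clusters — so every stage is validated against inputs whose
  answer is known exactly.

Structures and trajectories are read through
[bio3d](https://cran.r-project.org/package=bio3d) (PDB, DCD; GRO is parsed
natively, nm → Å), fits through `minpack.lm`, and every user-facing
function takes and returns tibbles so analyses compose with the pipe.

## Worked example

Generate an equilibrium trajectory of 2000 ideal substrate particles in a
square-well potential (−2 kT between 25 and 40 Å, hard core below 18 Å —
the signature of a surface-adsorbing substrate blocked at the pocket
entrance), then recover the planted landscape by Boltzmann inversion:

```r
library(subaccess)
library(dplyr)

pot  <- radial_potential(data.frame(r_lo = 25, r_hi = 40, u_kt = -2),
                         r_core = 18)
traj <- simulate_external_potential(pot, n_particles = 2000,
                                    n_sweeps = 400, burn_in = 150,
                                    frame_stride = 4, seed = 42)

profile <- replicate_set(list(traj)) |>
  dnac_series(synthetic_nac_spec()) |>
  bin_dnac_counts(bin_width = 1, d_max = 80) |>
  free_energy_profile(calibration_min = 60)

filter(as_tibble(profile), bin_lo %in% c(17, 18, 30, 39, 70)) |>
  select(bin_lo, bin_hi, count, dG_kT, flag)
#> # A tibble: 5 × 5
#>   bin_lo bin_hi count     dG_kT flag
#>    <dbl>  <dbl> <int>     <dbl> <chr>
#> 1     17     18     0 Inf       unsampled
#> 2     18     19   107  -0.0766  ok
#> 3     30     31  1933  -1.97    ok
#> 4     39     40  3314  -1.99    ok
#> 5     70     71  1447  -0.00557 ok
```

The profile reads exactly as planted: no particle below the 18 Å core
(`unsampled`), a −2 kT plateau across the well, and a flat far field
(the fitted bulk concentration, here 617 mM, is reported in
`attr(profile, "bulk_fit")`). `autoplot(profile)` draws it.

Saturable surface binding, from synthetic occupancies of 12 sites with a
planted binding constant of 7.4 mM:

```r
occ <- generate_langmuir_occupancy(K_true = 7.4, n_sites = 12, seed = 1) |>
  group_by(concentration_mM) |>
  group_map(~ mean_occupancy(.x, .y$concentration_mM)) |>
  purrr::list_rbind()
occ
#> # A tibble: 4 × 5
#>   concentration_mM mean_bound se_bound n_replicates n_frames
#>              <dbl>      <dbl>    <dbl>        <int>    <int>
#> 1                3       3.46    0.701            5  1000000
#> 2                5       4.84    0.760            5  1000000
#> 3               25       9.26    0.651            5  1000000
#> 4               50      10.5     0.519            5  1000000

fit <- fit_langmuir(occ)
tidy(fit, conf.int = TRUE)
#> # A tibble: 2 × 5
#>   term  estimate std.error conf.low conf.high
#>   <chr>    <dbl>     <dbl>    <dbl>     <dbl>
#> 1 K         7.40  0.00113      7.40      7.41
#> 2 bmax     12.0   0.000550    12.0      12.0
```

The fitted binding constant is the half-saturation concentration:
`predict(fit, fit$K_mM)` returns exactly `bmax / 2`.

Full analyses (multi-concentration access track, or the in-pocket complex
track with clustering and contact profiles) run from a single call —
`run_access_track()` / `run_complex_track()` in R, or
`Rscript inst/cli/subaccess.R run --config run.yaml` from a shell — and
write CSV/JSON outputs next to a manifest recording every parameter,
discarded replicate and fitted bulk concentration. See the vignette
(`vignettes/substrate-access.Rmd`) for the model, the defaults and their
rationale, and known limitations.

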