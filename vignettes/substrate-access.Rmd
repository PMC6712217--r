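---
title: "Methods: substrate access, binding and pose analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substrate access, binding and pose analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

subaccess analyses equilibrium molecular-dynamics trajectories of an enzyme
immersed in substrate solution. Its target system is the class of
amidohydrolases — cephalosporin acylase is the motivating case — where
turnover requires the substrate to (1) reach the protein surface from bulk,
(2) cross the entrance of a deep binding pocket, and (3) settle into a
productive near-attack pose against a catalytic serine. Each of those steps
leaves a statistical signature in unbiased trajectories, and each module of
the package extracts one of them.

## The reaction coordinate

All analyses are organised along a single composite distance between the
substrate's reactive carbonyl group and the catalytic machinery. Four
catalytic distances define a near-attack conformation (NAC): d1 from the
catalytic serine hydroxyl oxygen to the substrate carbonyl carbon, and d2–d4
from three oxyanion-hole donor atoms to the substrate carbonyl oxygen. The
coordinate is their root mean square with the two interchangeable oxyanion
donors collapsed to their nearer member:

$$ d_\mathrm{NAC} = \sqrt{\tfrac{1}{3}\left(d_1^2 + d_2^2 +
   \min(d_3, d_4)^2\right)} $$

`compute_dnac()` implements the formula; `dnac_series()` evaluates it for
every frame and every substrate copy under the minimum-image convention.
Useful identities: when all four distances equal \(d\) the coordinate is
\(d\) itself (a bound productive pose sits near 2.2 Å); the value is bounded
between \(m/\sqrt{3}\) and \(m\) with \(m = \max(d_1, d_2, \min(d_3, d_4))\);
and it is monotone in each input. At large separations all four distances
converge, so \(d_\mathrm{NAC}\) smoothly becomes "distance of the substrate
from the active site" and can be treated as a radial coordinate — an
approximation discussed below.

Donor atoms are configured as explicit atom indices rather than residue
names so that active-site mutants (e.g. a His-to-Ser substitution in the
oxyanion hole) are handled entirely by configuration.

### Kinetic-trapping filter

Bound-substrate simulations occasionally freeze in their starting pose; the
coordinate then never leaves its initial value and the run carries no
information about the pocket's equilibrium. `discard_trapped_replicates()`
drops replicates whose d_NAC range stays below `min_range` (default 1.0 Å).
The default must only separate "frozen" from "mobile": mobile bound runs
span roughly 2.2–13 Å, an order of magnitude above the threshold, so the
filter is insensitive to its exact value. Discards are recorded with their
observed range and surface in every manifest.

## Free energy profiles by Boltzmann inversion

At equilibrium the probability of finding a substrate molecule at a given
d_NAC is Boltzmann-distributed, so the enzyme's influence can be expressed
per 1 Å bin as

$$ \Delta G(i)/kT = -\ln\frac{p(i)_\mathrm{enzyme}}{N(i)_\mathrm{ref}}, $$

with \(p(i)\) the observed fraction of molecule-frame observations in bin
\(i\) and \(N(i)_\mathrm{ref}\) the count expected in the same bin for an
enzyme-free ideal solution at bulk concentration \(c\):

$$ N(i)_\mathrm{ref} = \tfrac{4}{3}\pi\left((a_i + \delta b)^3 - a_i^3\right)
   \, c \, N_A, $$

where \(a_i\) is the lower bin edge, \(\delta b\) the bin width, and
concentrations convert to number densities via
\(1\,\mathrm{mM} = 6.022\times 10^{-7}\) molecules/Å\(^3\).

Two numerical choices deserve explanation:

* **Scale calibration.** A normalised probability divided by an absolute
  count is not dimensionless; the mismatch is absorbed by construction into
  the one free scale parameter. Beyond ~60 Å the enzyme cannot influence the
  substrate, so `fit_bulk_concentration()` fits observed per-frame bin
  counts to the shell volumes over all bins past `calibration_min`
  (unweighted least squares through the origin, one parameter). The slope
  *is* the equilibrated bulk concentration in mM — typically below the
  nominal loading because part of the substrate has adsorbed to the protein
  — and the profile approaches 0 kT in the far field by construction. The
  fit is unweighted over all far-field bins by default; both the weighting
  and the bin range are exposed as options because neither choice is
  canonical.
* **Shells in a composite coordinate.** Treating d_NAC iso-surfaces as
  spheres is exact only at large distances where the coordinate degenerates
  to a centre distance. Near the active site the iso-surfaces are distorted;
  the shell-volume reference inherits that distortion. This is a property of
  the method being implemented, documented rather than corrected — profile
  features below ~10 Å should be read as relative populations, not absolute
  volumes.

Bins with zero observed count receive \(\Delta G = +\infty\) and the flag
`"unsampled"`. They are data: a contiguous unsampled region below a sampled
barrier (no molecule below 18 Å in the access simulations the method was
designed around) is the signature of an entrance barrier not crossed within
the simulation time.

Counts are pooled over replicates and substrate copies before inversion
(each molecule-frame observation contributes once); the profile is invariant
under duplicating all counts, because only ratios enter after the scale
refit. For pocket-confined simulations there is no bulk phase and no
meaningful reference, so `relative_free_energy_profile()` inverts raw bin
probabilities and shifts the global minimum to 0 kT; such profiles are
comparable only within themselves.

## Surface binding and the Langmuir isotherm

`bound_count_per_frame()` counts a substrate copy as bound near the pocket
entrance when its centre of mass lies within `contact_radius` (default 5 Å)
of at least one protein atom that itself lies within `site_radius` (default
25 Å) of the catalytic serine hydroxyl oxygen. The qualifying atom set is
recomputed each frame because the protein breathes; a `static_site` variant
freezes it on the first analysed frame for speed. "Any protein atom"
includes hydrogens when the topology has them; `heavy_only` restricts to
heavy atoms, since the convention is not fixed by the criterion itself.

Replicate averaging (`mean_occupancy()`) reports the unweighted mean over
replicates of per-replicate time means. The standard error propagates the
per-replicate standard deviations \(s_r\) of the frame counts through that
average, \(SE = \sqrt{\sum_r s_r^2}/R\). Frames within a replicate are
autocorrelated, so this SE describes scatter, not an effective-sample-size
corrected uncertainty; replicate-to-replicate scatter is the error measure
of choice here, which is why at least two replicates are required for an SE
at all.

Occupancies at several bulk concentrations are fitted to the saturable
non-cooperative isotherm

$$ \mathrm{bound}(c) = \frac{b_\mathrm{max}\, c}{K + c} $$

by Levenberg–Marquardt nonlinear least squares (`minpack.lm`), with starting
values \(b_\mathrm{max} = \max(\mathrm{bound})\), \(K = \mathrm{median}(c)\).
\(K\) is the half-saturation concentration: the fitted curve at \(c = K\)
yields exactly \(b_\mathrm{max}/2\), an identity used as a self-test. The
concentrations entering the fit default to the equilibrated bulk values
fitted from each profile's far field, not the nominal loadings
(`use_fitted_bulk = FALSE` overrides). Confidence intervals are Wald
intervals with a t quantile on the fit's residual degrees of freedom;
profile-likelihood intervals are ill-conditioned on the near-exact data the
generators produce, and the coverage experiment below shows the Wald
intervals hold their nominal level in the regime the package targets.
Non-convergence and non-positive optima raise errors rather than returning
a silently meaningless isotherm.

## Pose extraction, superposition, clustering, contacts

`extract_conformers()` collects every molecule-frame observation inside an
open d_NAC window together with the protein Cα coordinates of its frame.
`superpose_conformers()` then applies a Kabsch fit (SVD with reflection
guard, so the rotation determinant is always +1) of each frame's Cα atoms
onto a common reference and carries the substrate along. Conformer–conformer
RMSD is computed over all substrate atoms *without* per-pair refitting — the
protein frame defines the superposition once, so rigid substrate motion
relative to the protein counts as conformational difference, which is
exactly what distinguishes binding poses.

Clustering uses the gromos neighbour-counting algorithm: the conformer with
the most neighbours within `cutoff` RMSD seeds a cluster, the cluster is
removed, and the procedure repeats; ties break to the lowest conformer
index, making results deterministic. The cutoff is not canonical; the
default of 1.0 Å follows the conventional default of the clustering tools
used in this field and is always echoed in outputs. RMSD is unweighted
(not mass-weighted); for the small rigid-core substrates this analysis
targets, the difference is well below the cutoff granularity.

`contact_frequency()` reports, per protein residue, the fraction of frames
in which any residue atom lies within `cutoff` (default 4.0 Å, all-atom) of
any substrate atom. Persistent near-1 frequencies identify entrance
gatekeeper residues (access track) or pocket-trap residues (complex track).
Contacts are purely geometric; classifying them as electrostatic or
hydrophobic requires donor/acceptor typing that is out of scope. The
complex track profiles two windows by default, (2.5, 4.5) Å and
(8.5, 10.5) Å, bracketing the productive pose (~3.5 Å) and the in-pocket
trap (~9.5 Å) these analyses typically resolve.

## Synthetic ground truth

Because trajectories with known free-energy surfaces cannot be obtained
from real simulations, every stage is validated against generators whose
statistics are planted:

* `simulate_external_potential()` runs Metropolis Monte Carlo of
  non-interacting particles in a piecewise-constant radial potential around
  a fixed single-atom receptor in a periodic cube. Metropolis MC rather
  than Langevin dynamics, because only the equilibrium distribution
  \(\rho(r) \propto e^{-U(r)/kT}\) matters for Boltzmann inversion and MC
  requires no time-step or friction choices; frame order consequently
  carries no kinetic meaning, and no analysis in this package assumes it
  does. The default box (160 Å cube) guarantees far-field bins past 60 Å
  for the concentration calibration; the default square well (−2 kT between
  25 and 40 Å over an 18 Å hard core) reproduces the canonical signature of
  a surface-adsorbing, entrance-blocked substrate: a −2 kT surface plateau,
  a flat far field, and an unsampled core. The receptor atom doubles as the
  serine-oxygen anchor so the entire pipeline runs unchanged, with all four
  catalytic distances collapsing to the radial distance.
* `generate_langmuir_occupancy()` occupies each of `n_sites` identical
  sites independently per frame with probability \(c/(K+c)\); its defaults
  (12 sites, K = 7.4 mM, five replicates of 200 000 frames at 3, 5, 25 and
  50 mM) mirror the access-simulation protocol the analysis was designed
  for. Frames are independent by construction, which real trajectories are
  not — the generator validates estimator and fit, not autocorrelation
  handling.
* `generate_conformers()` draws conformers from k planted Gaussian clusters
  and hides them behind per-frame random rigid transforms of a carrier
  Cα scaffold, so that recovery requires a correct superposition. Defaults
  plant a 95 % / 5 % two-pose split of 500 conformers, emulating the
  situation where one dominant entrance-blocking pose coexists with a
  minority pose.

What passing these tests shows: the estimators are correct on data obeying
their own assumptions (equilibrium sampling, ideal-solution reference,
independent sites, rigid protein frame). What they do not show: robustness
to force-field error, incomplete convergence, protein conformational
drift, or solvent-mediated correlations — properties of real trajectories
that no desk-scale ground truth can emulate.

## Problem sizes and determinism

The validation suite runs the Monte-Carlo oracle with 5 000 particles, 200
burn-in sweeps and 100 stored frames (500 000 observations; step size 30 Å
with a stored frame every 4 sweeps, so successive frames of a particle are
essentially decorrelated and the per-bin standard error
\(1/\sqrt{\mathrm{count}}\) is an honest scale for the inversion check).
The Langmuir coverage experiment uses 100 generator seeds at the full
protocol size. All generators restore the caller's RNG state and echo their
full parameterisation (attribute `generator`), and pipeline manifests
record every analysis parameter, so any run can be reproduced from its
outputs alone.

## Conventions and limitations

* Units are Å, ps, kT and mM everywhere inside the package; converters live
  only at I/O boundaries (GRO nm → Å on read; CSV headers name units).
* Atom indices are 1-based, matching R and every structural package in its
  ecosystem; residue numbers and chain identifiers are preserved verbatim
  from input files (α/β-chain numbering such as "β369" maps to
  `chain_id = "B"`, `residue_number = 369`).
* Boxes are orthorhombic only; triclinic inputs are rejected at parse time.
* Trajectory formats: DCD and multi-model PDB are read (via bio3d), both
  are written; XTC is rejected with a pointer to conversion tools, since no
  reader for it exists in the package's dependency set.
* The shell reference is only valid up to half the box edge; histograms for
  periodic systems should set `d_max` accordingly (the generators' 160 Å
  box pairs with `d_max = 80`).
* Free energies are reduced (kT); no temperature parameter exists anywhere.
* Barrier heights are equilibrium quantities; the package deliberately
  offers no rate or residence-time estimation.
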