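---
title: "Modelling XFEL-induced disulfide dynamics in a screened plasma"
author: "plasmaMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling XFEL-induced disulfide dynamics in a screened plasma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A focused femtosecond X-ray free-electron-laser (XFEL) pulse ionizes every
atom in a protein nanocrystal many times over before the pulse ends.  The
ejected electrons either leave the sample or stay behind as a dense, hot
electron gas; the ions, suddenly charged, repel one another.  Disulfide
bridges are the most sensitive reporters of this local radiation damage:
sulfur is the heaviest common constituent of a native protein crystal, it
charges fastest, and the two bonded sulfurs sit only 2.08 Å apart.  Left
alone, an S–S pair carrying a couple of elementary charges each would fly
apart by several Ångström within 100 fs.  Inside the crystal two effects slow
this Coulomb explosion dramatically: *plasma screening* (the trapped electron
gas neutralizes the ion–ion interaction beyond the Debye length) and *ion
caging* (the surrounding, equally charged ions push the separating sulfurs
back).  plasmaMD implements a hybrid continuum model of this physics and a
pump–probe experiment driver that measures the mean S–S separation as a
function of the delay between two 15 fs pulses.

# The model, stage by stage

## Stage 1: atomic rates

Per-element, per-charge-state rates at the pulse photon energy (7.14 keV)
come from a small embedded table (`default_rate_table()`, a versioned JSON
resource that can be overridden by path):

* photoionization cross sections of the neutral atoms from standard
  photoabsorption tabulations, scaled across charge states by the remaining
  electron fraction (screened-hydrogenic electron counting);
* K-shell binding energies, total K-hole decay rates and fluorescence
  yields from standard compilations;
* successive ionization energies (`valence_binding`) from standard atomic
  data tables;
* electron-impact ionization in the Lotz form,
  $\sigma(E) = a\, n_v \ln(E/B) / (E B)$ with $a = 4.5\times10^{-14}$
  cm$^2$ eV$^2$ and $n_v$ outer-shell electrons, Maxwellian-averaged by
  numerical quadrature (`impact_ionization_rate()`); an exponential-integral
  closed form of the same average is the fast path inside the integrator and
  is tested against the quadrature and against Monte-Carlo sampling.

The charge-state scaling of the photo cross section is a documented tunable:
the photo channel contributes well under one event per light atom per pulse,
so its detailed scaling is immaterial next to the collisional channels.

## Stage 2: rate equations and the plasma state

`run_rate_equations()` integrates mean-field occupations $P_e(q,t)$ for each
element over charge states $q = 0\ldots Z$, plus a K-hole population per
element, a trapped-electron count, an electron energy budget and an escaped
charge, with classical RK4 at a fixed 0.02 fs step (internally halved if an
occupation would go negative; halving the step changes final mean charges by
under $10^{-3}$ relative, which the test suite asserts).

Electron bookkeeping follows a spherical-crystal trapping picture:

* **Photoelectrons** (KE = photon energy − binding) are tested, at birth and
  with their full energy, against the Coulomb barrier
  $k_e Q_\mathrm{net} / R$ of the net positive charge the crystal has
  accumulated (`electron_fate()`; $k_e = 14.3996$ eV Å, $R$ =
  `sample_radius`, default 1000 Å — a 100 nm-scale nanocrystal).  Electrons
  below the barrier are trapped and thermalize instantly; the rest escape
  and deepen the barrier for their successors.
* **Escaping photoelectrons ionize on their way out.**  A keV electron has an
  inelastic mean free path of order 10 nm in organic matter, so it leaves a
  trail of slow, locally trapped knock-on electrons along its escape chord
  (taken as $0.75 R$).  The channel uses the same Lotz cross sections at the
  photoelectron energy; its magnitude is consistent with textbook electron
  stopping powers (a few hundred eV deposited per escaping photoelectron at
  $R = 1000$ Å).
* **Auger electrons and impact-ionization secondaries** thermalize
  instantly into the trapped gas (the K-hole fluorescent branch consumes the
  hole without ionization; the photon is not tracked).

The trapped gas is a single-temperature bath, $T_e = \tfrac23 E/N$, and
supplies the inverse Debye screening length
$\kappa(t) = \sqrt{4\pi k_e n_e / T_e}$ (`screening_parameter()`), which is
zero for an empty plasma.  There is no recombination: charge staircases are
monotone, which is the main known source of charge-state overestimation of
continuum treatments with instantaneous thermalization.

Per-atom integer charge trajectories $Q_i(t)$ are realized from the
mean-field populations by a quantile coupling (`sample_ion_charges()`): each
atom draws an independent uniform level and carries the corresponding
quantile of its element's time-dependent charge distribution.  Because the
one-way rate equations shift that distribution monotonically upward, every
staircase is non-decreasing, the per-atom marginal matches the populations
exactly at every time, and atoms ionize independently — as they would in an
explicit stochastic treatment.  (A *mean-charge mode* assigning every atom
its element's real-valued mean is available for smoke tests.)

## Stage 3: screened ion dynamics

`integrate_ions()` moves the ions classically under pairwise forces
(fixed-step RK4, compiled kernel):

* screened Coulomb, $V_D = k_e Q_i Q_j e^{-\kappa r}/r$
  (`screened_pair_potential()`).  The screening parameter multiplies the
  distance in the exponent — the conventional Debye form, dimensionally the
  only consistent reading;
* a short-range collision wall $V_C = D(1 - e^{-a(r - r_e)})^2$ for
  $r \le r_e$, zero beyond (`collision_potential()`), acting **between ions
  only**: two neutral atoms do not interact at all (no bonded force field is
  included).  Defaults $D = 27.2$ eV, $a = 2$ Å$^{-1}$,
  $r_e$ = sum of covalent radii; all three are config-exposed, and the suite
  carries a sensitivity check only through the explicit parameters.

Because all charges are zero at $t = 0$, the initial state is exactly
force-free: the ions start at rest in their equilibrium positions.  Charges
are piecewise-constant staircases between rate-equation outputs (ionization
is a discrete event); $\kappa(t)$ is linearly interpolated (the bath is a
smooth property).

A spherical *free region* (radius `free_radius`, default 4.5 Å ≈ two
coordination shells) around the S–S midpoint is decided once at $t = 0$;
atoms inside move, all others stay frozen but keep exerting (charged)
forces — frozen ions are the caging environment.  The periodic replication
sum is truncated where $e^{-\kappa r}$ falls below `image_cutoff_tolerance`
(default $10^{-2}$), floored just above the collision contact radii and
capped at 12 Å: the cap binds only while the plasma is dilute, when the
ionic charges (which track the same ionization history) are correspondingly
small, and the residual far-replica contributions of the overall-positive
lattice largely cancel by symmetry.  The S–S distance uses the minimum-image
convention.

Numerical choices: RK4 step 0.02 fs by default (per-trajectory S–S endpoints
move by ~0.03 Å when the step is halved, far inside the ensemble spread; the
suite verifies fourth-order convergence and energy conservation below
$10^{-3}$ relative on frozen-charge runs at 0.01 fs), neighbour lists with a
1.5 Å skin, a tabulated $e^{-x}$ (relative error $\sim 10^{-7}$) in the
compiled kernel — the exported R reference implementations
(`total_force()`, `total_potential`) use exact exponentials and cross-check
the kernel in the tests.  A step displacing any atom by more than 0.5 Å
aborts with a suggestion to reduce the step.  Overlapping atoms (zero pair
distance) are refused by name.

# The pump–probe driver

`pulse_pair()` models two Gaussian profiles of equal FWHM (default 15 fs)
sharing the total fluence (default split 50/50), the pump centred at 20 fs
so its profile lies essentially inside the simulation window.
`run_experiment()` runs, per delay: the rate equations for the cell
composition (once — the mean field depends only on the composition), then
per trajectory a fresh seeded cell, charge-staircase sampling, and dynamics
up to the probe centre.  The observable is the tracked S–S distance at the
probe-pulse centre; a probe-Gaussian-weighted average is available
(`observable = "probe_weighted"`) since either convention is defensible for
a delay-resolved curve.  The master seed spawns per-trajectory seeds as
`(seed + 104729·delay_index + 7919·trajectory) mod (2^31 − 1)`, so any
single trajectory can be replayed.

Two modes:

* **dense** — the periodic supercell with screening from the rate-equation
  plasma;
* **vacuum** — the isolated four-atom disulfide moiety, ionized *exactly as
  in the dense crystal* (charges sampled from the same crystal-environment
  populations) but moving with no screening and no neighbours.  This is a
  deliberate design choice: the vacuum run isolates the mechanical effect of
  the dense environment (screening + caging) at matched ionization history.
  Ionizing the four atoms in true isolation would leave the moiety almost
  always neutral at the low fluence and there would be nothing to compare.

`elongation_speed()` converts the least-squares slope of the mean-distance
versus delay curve to m/s (1 Å/fs = $10^5$ m/s).  `displacement_ratio()`
compares the response at two fluences, by default as the ratio of mean
displacements from the initial bond length, optionally
(`type = "distance"`) as the ratio of mean distances.
`jackknife_dispersion()` attaches uncertainties: the standard deviation
across many means of random 75% subsets drawn without replacement, the
resampling scheme commonly applied to serial-crystallography image sets,
here applied to trajectory ensembles.

# Synthetic data

`generate_supercell()` emulates a 14 Å cube of solvated protein: ~300 atoms
(hydrogens included — only with hydrogens counted does that atom count match
solvated-protein density), one central cystine-like Cβ–Sγ–Sγ–Cβ motif with
the S–S bond at 2.08 Å (Cβ–Sγ 1.81 Å, 104° angles, 90° dihedral — standard
stereochemistry), the crystal's sulfur-to-light-atom ratio (2 S per 300
atoms by default), and H/C/N/O number fractions 0.52/0.15/0.04/0.29 of the
non-sulfur atoms (a solvated-protein average).  Placement is random with a
1.0 Å flat floor *and* a per-pair floor at the collision contact radius, so
the packed cell is force-free at any ionization state — without the latter,
random pairs born inside the repulsive wall would release tens of eV of
spurious potential energy the moment both partners ionize.  What the
generator does **not** emulate: real bonded topology and secondary
structure, solvent ordering, crystal contacts.  Passing tests therefore
demonstrate the ionization/screening/caging physics on a statistically
faithful medium, not predictions for a particular protein.

`generate_vacuum_disulfide()` builds the bare four-atom moiety (centre of
mass at the origin, zero momentum).  `cutout_from_pdb()` cuts a cube around
a named cystine bridge of a real structure (half-open `[0, edge)` boundary
rule; unsupported elements are dropped with a warning), for users who want a
structured environment instead of the random one.
`generate_reference_intensities()` draws acentric-Wilson (exponential)
intensities with mean $\propto e^{-2Bs^2}$, `s` uniform in reciprocal volume.

# Bragg termination

The diffraction-side damage observable is modelled by damping reference
intensities with an effective B-factor growing as the third power of time,
$B_\mathrm{eff}(t) = B_\mathrm{end}(t/t_\mathrm{pulse})^3$ (`b_eff()`),
applied as the intensity-convention Debye–Waller factor $e^{-2Bs^2}$ at each
of 100 uniformly spaced time points across a 100 fs pulse and averaged
(`attenuate()`).  Defaults $B_\mathrm{end} = 125$ Å$^2$ (native protein
case) or 500 Å$^2$ (heavy-atom-doped case).  Whether the cubic damping should
act on intensities or amplitudes is not uniquely fixed by convention; the
standard crystallographic intensity convention is used.  Diagnostics:
`wilson_fit()` (weighted least squares of $\ln\langle I\rangle$ versus
$s^2$ over 20 equal-volume resolution bins; empty or non-positive bins are
excluded, fewer than two usable bins is an error) and
`cumulative_intensity_distribution()` ($N(z)$ of bin-normalized intensities
against the ideal acentric $1 - e^{-z}$).

# Problem sizes

The test suite runs 20 trajectories per (fluence, delay) point — enough for
ensemble-level assertions with explicit standard-error allowances — and the
acceptance script (`scripts/acceptance.R`) 50 per point (100 for the cheap
vacuum ensemble), with rate equations at 0.02 fs and dynamics at 0.02 fs.
A full acceptance run takes a few minutes on one CPU core.

# Known limitations

* **No recombination.**  Charge states, especially of hydrogen, saturate
  high; the continuum model is expected to over-ionize relative to explicit
  stochastic treatments that include recombination.
* **Electron escape accounting.**  At the 100 nm default crystal radius the
  trapping barrier stays below the photoelectron energy at the lowest
  fluence, so nearly all photoelectron energy leaves the sample and the
  low-fluence plasma is fed mainly by Auger electrons and escape-path
  knock-ons.  A crystal embedded in a liquid jet, or a periodic-boundary
  treatment, would retain essentially all of that energy and charge the
  sample several times harder at low fluence.  `sample_radius` exposes this
  directly; the defaults are the package's stated study conditions.
* **Instantaneous thermalization** of trapped electrons; no electron-ion
  energy exchange after trapping, no spatially resolved electron cloud.
* **No bonded force field**: neutral atoms are transparent to each other,
  covalent bonds exert no restoring force.
* The free-sphere boundary freezes atoms beyond 4.5 Å of the bridge; their
  caging forces act, but their own recoil is suppressed.
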