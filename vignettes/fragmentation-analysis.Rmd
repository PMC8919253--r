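---
title: "Bond-integrity analysis of Coulomb-explosion ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-integrity analysis of Coulomb-explosion ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xplodeR)
```

## The problem

Soft X-ray absorption at the sulfur L-edge of a gas-phase biomolecular ion is
followed within femtoseconds by Auger decay, which raises the charge state and
triggers fragmentation. For protonated cystine — two cysteines joined by the
S1–S2 disulfide bridge, [C6H12N2O4S2 + H]+ at m/z 241.3 — the question is
*which bonds break*: ionization leaves the molecule in a +3 state whose
internal Coulomb repulsion tears it apart, and the fragment masses observed in
a time-of-flight spectrum encode the rupture sites.

xplodeR implements the full analysis chain for this experiment class:

1. a **molecular-graph / mass layer** (formulas, monoisotopic/average/nominal
   m/z, fragments as connected components after bond deletion);
2. a **surrogate trajectory generator** (thermalization plus microcanonical
   Coulomb-explosion runs) that produces ensembles with the statistical
   structure the analysis assumes;
3. the **bond-integrity analysis**: a per-bond statistic in [0, 1] referenced
   to thermalized baselines, break classification, ensemble break-probability
   tables and a fragment census;
4. an **ion-yield spectroscopy layer**: square-root-law TOF calibration, peak
   integration, partial/summed ion yields and Gaussian broadening of computed
   stick spectra.

## The integrity parameter

For a bond between atoms $A$ and $B$, the thermal reference distance is taken
from the thermalization run(s): $d_0 = \mu + \sigma$, where $\mu$ is the mean
and $\sigma$ the *population* standard deviation of the thermal bond-distance
series. Using a thermal-ensemble moment instead of the $t=0$ distance avoids
the lottery of picking a single fluctuating frame, and the one-sigma shift
accounts for the right skew of an anharmonic bond's thermal distribution — an
ordinary thermal excursion beyond the mean must not look like damage. (The
package's bonds are Morse potentials, so this skew is actually present; see
below.)

The per-frame integrity of the bond is

$$
\Xi(t) \;=\;
\begin{cases}
1, & d(t) \le d_0,\\[2pt]
\exp\!\big[-\big((d(t)-d_0)/\lambda\big)^2\big], & d(t) > d_0,
\end{cases}
$$

with decay scale $\lambda$ (default 0.5 Å). This clamped-Gaussian kernel is
the package's choice of smooth interpolant between the two physical
endpoints: it is exactly 1 for any distance inside the thermal envelope,
monotonically non-increasing beyond it, and indistinguishable from 0 once the
stretch exceeds a few $\lambda$ — at which point no realistic covalent bond
recovers. $\lambda = 0.5$ Å places the $\Xi = 0.5$ crossing about 0.42 Å
beyond $d_0$, roughly ten thermal standard deviations for a stiff bond at
300 K, so thermal noise never approaches the break region.

**Break classification.** The endpoint convention (1 intact, 0 broken) does
not by itself fix a decision rule, so the classifier is explicit: a bond is
*broken* when $\Xi < 0.5$ for **every** frame of the trailing 100 fs window.
The persistence window exists because a large transient stretch that recoils
is not a break; requiring the final window avoids counting such excursions
while matching the "state at the end of the run" reading of a 1 ps
simulation. Threshold, window and $\lambda$ are all arguments.

**Counting conventions.** Symmetry-equivalent bonds (e.g. C4–C6 and C1–C3)
are grouped into classes. By default a class counts as broken in a trajectory
if *any* member broke, with opportunities equal to the number of trajectories
(`counting = "trajectory"`); the alternative `"bond"` mode counts each member
separately. Both are exposed because grouped reporting does not uniquely
determine the convention; with 18 trajectories, 7 events map to 39% and 4
events to 22% in trajectory mode. Wilson 95% intervals accompany every
percentage — with 18 samples they are wide, which is the honest statement
about ensembles of this size.

**Census.** Fragmentation is read off the *final frame*: the bonds classified
broken are deleted from the molecular graph and the connected components are
the fragments. Intermediate recombination is deliberately ignored. Because a
classical trajectory cannot partition charge, fragments are reported as
neutral formulas plus the nominal m/z of the hypothetical +1 cation.

## The surrogate generator

The generator exists to exercise the analysis with realistic statistics — it
does not attempt electronic-structure forces (no DFT surfaces, no excited
states, no Auger dynamics). The potential is:

* **Morse bonds**, parameterised by a harmonic stiffness $k$ (curvature at
  the minimum), equilibrium length and well depth $D$, with width
  $a = \sqrt{k/2D}$. A strictly harmonic bond can never dissociate — the
  spring always pulls the fragments back — so an anharmonic, dissociative
  bond term is a requirement of the problem, and it is also what makes the
  thermal bond-length distribution right-skewed, the very property the
  $\mu + \sigma$ baseline is designed around.
* **Pairwise Coulomb** interactions on fixed partial charges
  ($k_C = 14.3996$ eV Å/e²), and
* a **short-range $(\sigma/r)^{12}$ repulsion** between non-bonded atoms.
  1–2 pairs are excluded from the non-bonded terms (standard
  molecular-mechanics convention). There are no angle or dihedral terms: the
  analysis consumes bond distances, and a floppy backbone is an acceptable
  price for a small, transparent parameter set.

Protocol defaults mirror the study conditions: 0.5 fs velocity-Verlet step,
thermalization near 300 K with a Berendsen-style weak-coupling rescale
($\lambda = \sqrt{1 + (\Delta t/\tau)(T_0/T - 1)}$, $\tau = 0.1$ ps), 1 ps
microcanonical production runs, ensembles of 18 starting configurations
sampled at least 1 ps apart from the thermal run. Initial velocities are
seeded Maxwell–Boltzmann draws (net momentum removed, kinetic energy rescaled
exactly to target); production runs inherit the sampled frame's positions and
velocities. Every source of randomness flows from one integer seed, and
per-trajectory seeds are derived as `seed + index`, so ensembles are
bit-reproducible.

**The ionized state.** The +3 charge left after ionization and Auger decay is
spread uniformly over the 14 heavy atoms plus the extra amine proton — a
classical surrogate has no unique charge distribution, and the uniform model
is the simplest defensible default (it is configurable). Ionization also
removes bonding electrons, which a ground-state force field cannot express;
the package models this destabilisation by scaling the Morse well depths of
the +3 force field (`depth_scale`, default 0.15). The default was fixed once,
when the generator was built, so that the +3 ensemble actually fragments the
ion within 1 ps — the regime the analysis is for — and is not otherwise
tuned; the three backbone bond classes then break at distinct, seed-stable
rates, which is what the analysis needs to see. The surrogate's break
percentages are *surrogate properties*: they are not, and are not meant to
be, the probabilities a Born–Oppenheimer treatment would give.

**Engineered ground truth.** For validation there is a configuration with a
*known* break probability: `recovery_force_field()` weakens only the two
carboxyl C–C bonds (factor 0.155, every other bond at full depth), and
`estimate_break_probability()` runs independent explosions from the relaxed
geometry with fresh 300 K Maxwell–Boltzmann velocities. The factor was
calibrated once, on development seeds, to put the class break probability at
0.5 over 0.5 ps runs (measured 0.505 over 200 independent runs) and then
frozen; the acceptance test draws 50 fresh runs and requires the event count
to land in the exact central 95% binomial band for $p = 0.5$, i.e. 18–32 of
50. Independent starts (rather than frames of one long thermal trajectory)
are used here because the floppy surrogate wanders conformationally on tens
of picoseconds, which makes frames from a single run strongly correlated; a
probability defined over i.i.d. draws is the quantity the binomial test
assumes.

## The spectroscopy layer

* **TOF calibration** fits $t = t_0 + k\sqrt{m/z}$ — the linear-TOF law —
  exactly through two reference peaks (typically m/z 45, COOH⁺, and m/z 64,
  SS⁺) and by least squares for more. The inverse
  $m/z = ((t - t_0)/k)^2$ round-trips to machine precision.
* **Peak integration** is trapezoidal over a window for dense spectra (with
  interpolated window edges) and a plain sum for peak lists. The default
  fragment windows are ±0.5 m/z around nominal values, matching
  unit-resolution spectra; window widths and background treatment are
  declared defaults, not inferred quantities.
* **PIY/SIY.** A partial ion yield is the windowed integral of one fragment
  peak as a function of photon energy; the scan validates its grid spacing
  against the 40–70 meV protocol. The summed ion yield is the exact
  elementwise sum of the stored PIY arrays — an identity, not an
  approximation — and serves as the absorption-spectrum proxy.
* **Stick broadening.** Computed transitions are shifted rigidly (default
  7.23 eV) and convolved with a unit-area Gaussian (default FWHM 0.7 eV,
  $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$) on a grid of spacing FWHM/20, which
  keeps quadrature error on the conserved area below 0.1%. Both numbers are
  *match parameters* aligning a calculated spectrum with a measured one, so
  they are arguments with defaults, not constants.

## Masses and m/z

Monoisotopic masses and IUPAC average atomic weights are embedded for
H, C, N, O, S; an electron mass (0.000549 u) is subtracted per positive
charge whenever a charge is set (toggleable). This correction is what makes
the five-decimal monoisotopic values of the isobaric m/z 74 pair come out at
74.00590 (C2SNH4⁺) and 74.02365 (C2O2NH4⁺). *Nominal* m/z is defined as the
average mass rounded to the nearest integer, which reproduces the integer
peak labels of unit-resolution spectra — including m/z 64 for the disulfide
cation, whose average mass is 64.12.

The cystine fixture is built with explicit hydrogens (27 atoms, 26 bonds, a
tree), because the H-count families C2NH$_x$⁺ and CSH$_x$⁺ differ only in
hydrogens. The two amine sites are symmetric and the extra proton's location
is arbitrary between them; it defaults to N1 and is configurable. The fixture
geometry is a deliberately rough extended build that is relaxed against the
force field before any dynamics.

## Numerical choices and degenerate inputs

* Population (not sample) standard deviation in baselines; fixed for
  reproducibility and because the baseline is a descriptive moment.
* Baselines pool the second half of each thermalization run (`burn_in =
  0.5`) so the equilibration transient does not inflate $\sigma$.
* Kinetic temperature uses $3N - 3$ degrees of freedom (net momentum is
  removed at initialisation).
* The thermostat scaling factor is clamped to [0.9, 1.1] per step, which
  keeps the weak-coupling limit well-behaved when the instantaneous
  temperature is far from target (including the cold-start case, where the
  system heats from residual strain).
* Integration aborts with the failing frame index on non-finite or runaway
  (> 10⁶ Å) coordinates.
* Zero-length integrity series, empty ensembles, inverted windows, duplicate
  calibration references and non-covered bonds are all hard errors.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: 2 ps
thermalizations for shared fixtures, 18-run ensembles of 1 ps explosions for
ensemble properties, 50 half-picosecond runs for the recovery check, and a
3 ps two-charge run for the closed-form Coulomb benchmark. These sizes were
chosen so the full chain — generator, baselines, classification, counting —
is exercised end to end with stable statistics.

## What passing tests do and do not show

The generator emulates the *statistical shape* of thermal-plus-explosion
trajectory data: equilibrated bond-length fluctuations with realistic
skewness, seeded ensemble variability, energy-conserving dissociation
dynamics, and fragment patterns tied to the molecular graph. It does not
emulate electronic-structure forces, charge migration, excited-state
dynamics or secondary fragmentation kinetics. Green tests therefore certify
the *analysis*: that the integrity statistic honors its contract, that break
counting and rounding are correct at known event counts, that an engineered
known probability is recovered, and that the mass and spectroscopy layers
reproduce their closed-form targets. They do not certify any particular
physical break probability for cystine — that is what the original
electronic-structure simulations are for.

## A minimal run

```{r example, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(n_configs = 18, seed = 1))
res <- run_pipeline(cfg, out_dir = "cystine_run")
res$break_table
autoplot(res$break_table)
```
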