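---
title: "Discriminating catalytic mechanisms of PhzF on surrogate energy surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating catalytic mechanisms of PhzF on surrogate energy surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phzfmech)
```

## The scientific problem

PhzF (E.C. 5.3.3.17) isomerizes (2S,3S)-2,3-dihydro-3-hydroxyanthranilic
acid (DHHA) to the aminoketone AOCHC in two chemical steps: a suprafacial
[1,5]-shift of the non-acidic C3 proton to C1, forming the enol
intermediate AHCDC, followed by a stereospecific keto-enol
tautomerization. The proton shift could proceed either as a concerted
sigmatropic rearrangement (one pericyclic transition state) or as
stepwise acid/base catalysis in which the conserved glutamate E45
abstracts the C3 proton and re-delivers the *same* proton at C1. The two
hypotheses are distinguished quantitatively: by the activation barriers
of candidate reaction paths, by the protonation state (pKa) of E45 in
the complex, and by the magnitude of the primary kinetic isotope effect
(KIE) when C3 carries deuterium.

`phzfmech` re-implements this mechanism-discrimination analysis as a
tested pipeline operating at desk scale. Electronic-structure theory is
out of scope: all path optimization, vibrational classification and
zero-point arithmetic run on **surrogate energy surfaces** whose
stationary-point energies are prescribed inputs, and the
continuum-electrostatics titration is replaced by a screened-Coulomb
multi-site model. What the package reproduces is the *method chain* --
scan, nudged elastic band (NEB), conjugate peak refinement (CPR),
Hessian classification, zero-point correction, Metropolis titration,
transition-state theory, Michaelis-Menten kinetics -- together with the
headline arithmetic that links them.

## Surrogate surfaces

A `mechanism_spec` lists alternating minima and first-order saddles with
energies (kcal/mol) relative to the first minimum, one transverse
wavenumber per stationary point, and the reactive-mode wavenumber
(default 2448 cm^-1, whose half-quantum of 3.5 kcal/mol is exactly the
zero-point reduction that takes the raw 17.8 kcal/mol deprotonation
barrier to 14.3 kcal/mol).

`make_mechanism_surface()` builds V(xi, y) = V1(xi) + k(xi) y^2 / 2.
The backbone V1 is constructed segment-wise through its *derivative*: on
each inter-node segment the derivative is the cubic
d(u) = sgn * u (L - u)(p + q u) with p, q fixed by the prescribed
curvatures at the two nodes and the segment length
L = sqrt(12 |dE| / (S_left + S_right)) fixed by the energy difference.
This derivative has no interior zero, so V1 is strictly monotone between
stationary points -- no spurious wells or saddles -- while energies,
zero gradients and curvatures at the nodes are exact and V1 is C2.
Two dimensions (reaction coordinate plus one transverse mode) are the
minimal setting that exercises saddle classification, imaginary-mode
detection and transverse zero-point bookkeeping.

Wavenumbers and curvatures interconvert through
nu = 108.593 * sqrt(lambda / m) cm^-1 (lambda in kcal/mol/A^2, m in
amu), the package's single pinned frequency-conversion constant; all
physical constants live in `phzf_constants()`.

The canonical catalogue (`phzf_surface_spec()`) encodes the three
candidate shift paths at their computed barriers: sigmatropic 32.5,
concerted cationic 27.2, shuttle step-1 14.3 kcal/mol. Energies of
intermediates without anchored values are free parameters; the shuttle's
post-abstraction intermediate defaults to 8 kcal/mol, standing in for a
"high-lying" state, and is documented as such rather than presented as a
computed value.

## Path optimization and classification

* `scan_initial_path()` relaxes all non-scanned coordinates at each grid
  value (warm-started along the scan), bracketing the saddle from below.
* `neb_refine()` is standard NEB with the improved-tangent rule, springs
  acting along the tangent, an optional climbing image, and a FIRE
  optimizer. Defaults: 11 images, spring constant 1 kcal/mol/unit^2,
  perpendicular-force tolerance 1e-4, 5000 iterations, displacement cap
  0.1 per step. These defaults are package choices, not literature-prescribed
  values.
* `cpr_refine()` locates interior energy maxima of the piecewise-linear
  path, alternates maximization along the local path tangent with
  minimization in the conjugate (orthogonal) subspace, then polishes
  with Newton steps on the full gradient. Refined peaks are classified;
  anything of order >= 2 is flagged as a higher-order saddle, never
  silently accepted.
* `classify_stationary()` builds a central-difference Hessian (step
  1e-4), mass-weights it, and reports eigenvalues, the order (count of
  eigenvalues below -1e-8, a threshold that absorbs round-off) and
  harmonic wavenumbers with imaginary modes flagged.

On the analytic catalogue (quadratic bowl, 1-D/2-D double wells) both
CPR and climbing-image NEB agree with dense-grid brute-force saddle
searches to better than 1e-2 kcal/mol; on mechanism surfaces the
constructed stationary points are recovered to 1e-6 kcal/mol and 1 cm^-1.

## Multi-site titration

Protonation microstates s (s_i = 1 when site i is protonated) carry the
free energy

G(s; pH) = sum_i s_i ln(10) R T (pH - pKa_i) + sum_(i<j) W_ij s_i s_j

relative to the fully deprotonated state. `enumerate_titration()` is the
exact 2^n oracle (refused above 20 sites); `mc_titrate()` is the
Metropolis sampler, where one Monte Carlo step is one systematic scan of
single-site flips -- the convention of multi-site titration codes -- and
the default 1e5 steps per pH point reproduce the exact curves to a few
parts in a thousand. Reported Monte Carlo standard errors combine a
batch-means estimate (20 batches) with a Laplace-smoothed binomial floor
in quadrature; the floor keeps error bars meaningful at saturated sites
where batch variance collapses. The error bars are therefore mildly
conservative by design, yet over ~1700 grid-point estimates a few
fluctuations near 3-4 SE remain statistically inevitable.

`build_sites_from_structure()` makes a site model from a PDB file:
standard model pKas (His fixed in the N-epsilon tautomer), one
representative charged atom per residue, and the screened-Coulomb
surrogate W_ij = 332.06 q_i q_j exp(-kappa r_ij) / (eps r_ij) with a
single effective dielectric (default 20) replacing the
Poisson-Boltzmann step, which is deliberately out of scope. Because the
interaction acts between *protonated* forms referenced to the fully
deprotonated state, couplings among anionic (acid) sites vanish in this
surrogate -- a documented limitation, acceptable for the cationic and
mixed pairs it is used for here.

`convert_pka_energy()` implements dG = ln(10) R T (pKa - pH) and the
pH-independent gap conversion; these carry the headline arithmetic
(1.7 kcal/mol at pH 7.5 <-> pKa ~9; a 12.3-unit gap <-> ~17 kcal/mol).

`simulate_titration()` integrates the exact charge balance of a
polyprotic analyte titrated with strong base. The analyte is modeled as
dissolved in its fully protonated form with inert counter-ions (an acid
salt): titrating the neutral zwitterion would start at the isoelectric
point and never probe the acidic group, so the salt convention is what
makes a two-plateau curve -- and a two-pKa fit -- possible from a single
NaOH titration.

## Rates and isotope effects

`eyring_rate()` is k = (k_B T / h) exp(-dG/RT) with transmission
coefficient 1. `harmonic_zpe()` is the half-quantum sum with
h c = 2.8591e-3 kcal/mol per cm^-1. `isotope_scale()` scales X-H
stretches by the diatomic reduced-mass ratio, and
`semiclassical_kie_limit()` gives the textbook ceiling for C-H cleavage
(~7 for a 3000 cm^-1 stretch at 298.15 K) from complete loss of the
stretch zero-point energy at the transition state. `kie_from_ddg()`
defaults to 288.15 K because the intrinsic KIE of 4.8 for a 0.9 kcal/mol
deuteration penalty is reproduced at 15 degrees C (the NMR temperature);
at 298.15 K the same penalty gives 4.57, and both are exposed. Tunneling
is not modeled anywhere; the package's role for the measured-vs-ceiling
comparison is purely arithmetical.

## Photometric kinetics

The simulator integrates d[S]/dt = -v_max E [S]/(K_M + [S]) (deSolve)
with the enzyme dosed as a homodimer, emits A(t) = eps l [S](t) plus
additive Gaussian noise (plate-reader shot-noise approximation, default
0.002 absorbance units), and prepends an instrument lag (default 30 s).
Unit chain: specific activity (nmol s^-1 mg^-1) x enzyme mass
concentration (mg/ml) = uM/s; k_cat = v_max x molar mass x 1e-6. The
monomer molar mass default of 32 200 g/mol is *derived* from the four
shipped (v_max, k_cat) pairs by regression through the origin, since
the pairs are reported without a mass, and stays a parameter.
The optical path of 0.29 cm is the approximate height of 100 ul in a
96-well plate, again a parameter, because fitted rates are shipped
pre-converted.

`extract_initial_rate()` discards a fixed 60 s pre-linear phase, detects
any longer lag with a BIC-gated continuous hinge changepoint, and fits
the first post-lag window that passes two gates: linearity (R^2 >= 0.2)
and slope significance (t >= 5 against the photometric noise), escalating
through window widths (120, 240, 480 s, full trace) so that slow wells
accumulate enough signal. Windows longer than 300 s get a first-order
curvature correction (quadratic refit, derivative at the window start)
to remove substrate-depletion bias. The window is chosen by *position*,
not by maximizing R^2 across all windows: the R^2-maximal window is
systematically noise-steepened and was measured here to overestimate
rates by 5-8% at this noise level, enough to corrupt parameter recovery.

`fit_michaelis_menten()` is unweighted nonlinear least squares
(Levenberg-Marquardt via minpack.lm) with 1/v weighting behind a flag;
`apparent_kie()` propagates first-order errors through v_max and
v_max/K_M ratios using each fit's covariance, reporting 2 significant
figures. The default simulated design is 8 two-fold dilutions from
1000 uM in triplicate, the package's reading of "up to 1 mM".

## Catalytic-cycle profile

Only text-anchored energies enter the canonical profile: the
zero-point-corrected C3-deprotonation transition state at 14.3 kcal/mol,
the +1.7 kcal/mol penalty for first deprotonating E45 (raising the
overall barrier to 16.0), the enol-complex minimum at -11.5 kcal/mol and
the water/E45 relay tautomerization transition state 9.2 kcal/mol above
it. Whether the -11.5 minimum already contains the +1.7 correction is
ambiguous; `phzf_profile()` defaults to the as-reported convention (`"minima_uncorrected"`, correction on
transition states only) and offers `"correct_all"`, recording the active
convention on the object. `rank_mechanisms()` sorts candidates by
overall barrier and rules out anything above 25 kcal/mol -- a repository
convention for enzyme-relevant rates, not a sourced number. The optional
E45D scenario adds a user-chosen >= 15 kcal/mol penalty to the shuttle's
deprotonation step; no exact increment is anchored, so it stays a
parameter.

## What the generators do and do not emulate

The synthetic data reproduce: prescribed stationary-point energies and
harmonic frequencies; Michaelis-Menten depletion with lag and Gaussian
photometric noise; exact acid/base charge balance with pH-reading noise;
and random coupled site systems. They do not emulate anharmonicity,
recrossing or tunneling, instrument drift or pipetting error, activity
loss of the enzyme, or conformational (open/closed) coupling of site
pKas -- the open-versus-closed pKa contrast is represented as two
separate site-model configurations, not as a conformational model.
Passing tests therefore demonstrate correctness of the algorithms under
the stated noise models, not the accuracy of any electronic-structure
result.

## Problem sizes and numerical choices

The shipped analyses use 41-point scans, 11-15 NEB images, 2^12-state
enumerations against 1e5-step Monte Carlo runs, and kinetics designs of
24 traces per isotopologue (241 time points each); the full canonical
pipeline (`run_pipeline()`) completes in well under a minute on one CPU.
Tolerances: NEB force 1e-4, CPR gradient 1e-8 with Newton polishing,
Hessian step 1e-4, eigenvalue negativity -1e-8, ODE integration at
rtol = atol = 1e-10. Ties in `overall_barrier()` and `rank_mechanisms()`
break by first occurrence. Degenerate inputs (flat traces, locked
titration sites, saddle-free surfaces, monotone paths) return the
documented zero/error outcomes rather than fabricated estimates.

## Known limitations

Surrogate surfaces carry abstract coordinates, not atomic Cartesians;
barriers are inputs, not predictions. The screened-Coulomb site model
omits desolvation self-energies and acid-acid coupling. Single-site
Metropolis flips mix slowly for very strongly coupled pairs (no
double-site moves). Initial-rate extraction assumes depletion (falling
absorbance); progress-curve (integrated rate-law) fitting is
deliberately not provided.
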