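# phzfmech

Mechanism discrimination for the PhzF-catalyzed isomerization of DHHA,
as a tested R pipeline on surrogate energy surfaces.

PhzF, a cofactor-free isomerase of phenazine biosynthesis, converts
(2S,3S)-2,3-dihydro-3-hydroxyanthranilic acid (DHHA) to an aminoketone
in two steps: a suprafacial [1,5]-shift of the C3 proton to C1, then a
stereospecific tautomerization. The shift could be a concerted
sigmatropic rearrangement or stepwise acid/base catalysis with the
conserved glutamate E45 shuttling the proton. `phzfmech` implements the
quantitative machinery that separates these hypotheses:

* **Reaction paths** — potential-energy-surface scans, nudged elastic
  band with climbing image, conjugate peak refinement (CPR), and
  mass-weighted Hessian classification of minima vs first-order saddles,
  on 2-D surrogate surfaces with prescribed stationary energies.
* **Protonation states** — multi-site titration with the microstate
  energy `G(s; pH) = Σᵢ sᵢ ln10·RT·(pH − pKaᵢ) + Σᵢ<ⱼ Wᵢⱼ sᵢ sⱼ`, exact
  2ⁿ enumeration, Metropolis Monte Carlo, and pKa ↔ free-energy
  conversion `ΔG = ln10·RT·(pKa − pH)`.
* **Rates and isotope effects** — Eyring rates
  `k = (k_B T/h)·exp(−ΔG‡/RT)`, harmonic zero-point energies
  `ZPE = Σ ½hcν`, reduced-mass isotope scaling, `KIE = exp(ΔΔG‡/RT)`,
  and the semiclassical C–H/C–D KIE ceiling (≈7).
* **Enzyme kinetics** — simulation of 275-nm substrate-depletion plate
  assays (ε = 6500 M⁻¹cm⁻¹), initial-rate extraction, Michaelis–Menten
  fits `v = v_max·S/(K_M + S)` with `k_cat = v_max·M·10⁻⁶`, apparent
  KIEs on v_max and v_max/K_M with propagated errors, and multi-site
  pKa fits to acid/base titrations.
* **Profiles** — catalytic-cycle free-energy assembly with the
  glutamate-deprotonation correction, rate-limiting-step identification,
  mechanism ranking, and TST-vs-experiment consistency checks.

## Worked example

```r
library(phzfmech)

rank_mechanisms(phzf_candidates("shift"))
#>          name overall_barrier   verdict
#> 1     shuttle            16.0 plausible
#> 2   concerted            27.2 ruled out
#> 3 sigmatropic            32.5 ruled out

ob <- overall_barrier(phzf_profile())
ob$barrier; ob$limiting_step
#> [1] 16
#> [1] "C3 deprotonation"

signif(kie_from_ddg(0.9), 3)          # intrinsic KIE at 288.15 K
#> [1] 4.82
round(semiclassical_kie_limit(3000), 2)
#> [1] 6.87
round(convert_pka_energy(1.7, "energy_to_pka", pH = 7.5, T = 298.15), 2)
#> [1] 8.75

tst <- tst_consistency(phzf_profile(), 3.23)
round(tst$ratio, 2); tst$verdict
#> [1] 3.6
#> [1] "consistent within one order"
```

Reading: the E45 proton-shuttle path (14.3 kcal/mol step barrier plus a
1.7 kcal/mol penalty for deprotonating the glutamate first) is the only
candidate below the 25 kcal/mol plausibility cutoff; C3 deprotonation is
rate limiting at 16.0 kcal/mol. A 0.9 kcal/mol deuteration penalty on
that step predicts an intrinsic KIE of ≈4.8, below the ≈7 semiclassical
ceiling, while the Eyring rate of the 16.0 kcal/mol profile sits within
a factor of ~3.6 of the measured k_cat of 3.23 s⁻¹. The 1.7 kcal/mol
deprotonation energy at pH 7.5 corresponds to a glutamate pKa of ≈9.

The full chain — surface construction, CPR, titration, simulated
kinetics with Michaelis–Menten fits and apparent KIEs, profile assembly
— runs as one call:

```r
report <- run_pipeline(run_config(out_dir = "out", seed = 1))
```

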