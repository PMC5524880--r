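#' Eyring transition-state-theory rate
#'
#' k = (k_B T / h) exp(-dG / (R T)), transmission coefficient 1.
#'
#' @param dG activation free energy, kcal/mol.
#' @param T temperature, K.
#' @return rate constant, s^-1.
#' @export
eyring_rate <- function(dG, T = 298.15) {
  if (any(T <= 0)) stop("temperature must be positive")
  .const$kB_over_h * T * exp(-dG / (.const$R_kcal * T))
}

#' Kinetic isotope effect from a barrier difference
#'
#' KIE = exp(ddG / (R T)), where ddG is the increase of the activation
#' free energy on heavy-isotope substitution. The default temperature is
#' 288.15 K (15 degrees C, the NMR condition under which the intrinsic KIE
#' of 4.8 for 0.9 kcal/mol is reproduced); at 298.15 K the same ddG gives
#' 4.57.
#'
#' @param ddG activation free-energy increase, kcal/mol.
#' @param T temperature, K (default 288.15).
#' @return dimensionless KIE.
#' @export
kie_from_ddg <- function(ddG, T = 288.15) {
  if (any(T <= 0)) stop("temperature must be positive")
  exp(ddG / (.const$R_kcal * T))
}

#' Harmonic zero-point energy
#'
#' ZPE = sum_i h c nu_i / 2 over the real vibrational modes, with
#' h c = 2.8591e-3 kcal/mol per cm^-1.
#'
#' @param wavenumbers real mode wavenumbers, cm^-1 (all > 0).
#' @return zero-point energy, kcal/mol.
#' @export
harmonic_zpe <- function(wavenumbers) {
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) == 0) stop("at least one mode is required")
  if (any(wavenumbers <= 0)) stop("wavenumbers must be positive")
  sum(.const$hc_kcal * wavenumbers / 2)
}

#' Scale X-H stretch wavenumbers on isotope substitution
#'
#' Each mode is scaled by sqrt(mu_light / mu_heavy) with the diatomic
#' reduced mass mu = m_X m / (m_X + m), the standard local-mode model for
#' C-H versus C-D stretches.
#'
#' @param wavenumbers mode wavenumbers, cm^-1.
#' @param mass_light light-isotope mass, amu (default 1, H).
#' @param mass_heavy heavy-isotope mass, amu (default 2, D).
#' @param heavy_atom_mass mass of the bonded heavy atom, amu (default 12,
#'   carbon); `Inf` gives the pure sqrt(m_light/m_heavy) limit.
#' @return scaled wavenumbers, cm^-1.
#' @export
isotope_scale <- function(wavenumbers, mass_light = 1, mass_heavy = 2,
                          heavy_atom_mass = 12) {
  if (any(c(mass_light, mass_heavy, heavy_atom_mass) <= 0))
    stop("masses must be positive")
  mu <- function(m) if (is.infinite(heavy_atom_mass)) m
    else heavy_atom_mass * m / (heavy_atom_mass + m)
  as.numeric(wavenumbers) * sqrt(mu(mass_light) / mu(mass_heavy))
}

#' Semiclassical upper limit of a primary KIE
#'
#' KIE limit from complete loss of the X-H stretch zero-point energy at
#' the transition state: exp(h c (nu_H - nu_D) / (2 R T)), with nu_D from
#' [isotope_scale()]. For a 3000 cm^-1 C-H stretch at 298.15 K this is
#' about 7, the classical ceiling for C-H bond cleavage; larger measured
#' intrinsic KIEs indicate tunneling.
#'
#' @param stretch_wavenumber light-isotope stretch, cm^-1.
#' @param heavy_atom_mass bonded heavy-atom mass, amu (default 12).
#' @param T temperature, K.
#' @param mass_light,mass_heavy isotope masses, amu.
#' @return dimensionless KIE limit.
#' @export
semiclassical_kie_limit <- function(stretch_wavenumber = 3000,
                                    heavy_atom_mass = 12, T = 298.15,
                                    mass_light = 1, mass_heavy = 2) {
  if (stretch_wavenumber < 0 || T <= 0) stop("inputs must be positive")
  nu_d <- isotope_scale(stretch_wavenumber, mass_light, mass_heavy,
                        heavy_atom_mass)
  exp(.const$hc_kcal * (stretch_wavenumber - nu_d) /
        (2 * .const$R_kcal * T))
}

#' KIE from reactant and transition-state mode sets
#'
#' Computes ddG = (ZPE_TS - ZPE_react)_heavy - (ZPE_TS - ZPE_react)_light
#' via [harmonic_zpe()] and returns [kie_from_ddg()] at the same
#' temperature, so the ZPE route and the barrier-difference route agree by
#' construction.
#'
#' @param react_light,ts_light real-mode wavenumbers of reactant and
#'   transition state, light isotopologue.
#' @param react_heavy,ts_heavy same for the heavy isotopologue.
#' @param T temperature, K.
#' @return dimensionless KIE.
#' @export
kie_from_zpe <- function(react_light, ts_light, react_heavy, ts_heavy,
                         T = 288.15) {
  z <- function(w) if (length(w) == 0) 0 else harmonic_zpe(w)
  ddg <- (z(ts_heavy) - z(react_heavy)) - (z(ts_light) - z(react_light))
  kie_from_ddg(ddg, T)
}
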