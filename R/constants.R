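#' Physical constants used throughout phzfmech
#'
#' All energies are kcal/mol, temperatures K, frequencies cm^-1, coordinates
#' abstract units interpreted as Angstrom, masses amu. Constants are pinned
#' here, in one place, so every module agrees on the arithmetic.
#'
#' @return Named list with elements:
#' \describe{
#'   \item{R_kcal}{gas constant, 1.9872e-3 kcal mol^-1 K^-1}
#'   \item{ln10}{natural log of 10, 2.302585}
#'   \item{kB_over_h}{Boltzmann/Planck ratio, 2.0837e10 s^-1 K^-1}
#'   \item{hc_kcal}{h*c, 2.8591e-3 kcal/mol per cm^-1 of wavenumber}
#'   \item{freq_conv}{wavenumber of a mode with unit mass-weighted force
#'     constant: 108.593 cm^-1 per sqrt(kcal mol^-1 amu^-1 A^-2)}
#' }
#' @export
phzf_constants <- function() {
  list(
    R_kcal    = 1.9872e-3,
    ln10      = log(10),      # 2.302585...
    kB_over_h = 2.0837e10,
    hc_kcal   = 2.8591e-3,
    freq_conv = 108.593
  )
}

.const <- phzf_constants()
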