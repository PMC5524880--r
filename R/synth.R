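#' Photometric assay parameters
#'
#' Parameter set for simulating substrate-depletion traces at 275 nm. The
#' substrate absorbs (extinction coefficient `epsilon_275`); the product is
#' photometrically silent. Specific activity is expressed per mg of
#' enzyme; the enzyme is dosed as a homodimer.
#'
#' @param v_max maximal specific activity, nmol s^-1 mg^-1.
#' @param K_M Michaelis constant, uM.
#' @param substrate_conc_0 initial substrate, uM.
#' @param enzyme_conc enzyme dimer concentration, nM.
#' @param epsilon_275 extinction coefficient, M^-1 cm^-1 (default 6500).
#' @param path_length optical path, cm; default 0.29, the approximate
#'   height of 100 ul in a 96-well plate.
#' @param noise_sd additive Gaussian absorbance noise (default 0.003).
#' @param lag_time instrument lag before turnover is observed, s.
#' @param temperature K.
#' @param monomer_mass enzyme monomer molar mass, g/mol (default 32200).
#' @param seed integer seed for the noise.
#' @return object of class `assay_params`.
#' @export
assay_params <- function(v_max = 100.34, K_M = 517, substrate_conc_0 = 1000,
                         enzyme_conc = 40, epsilon_275 = 6500,
                         path_length = 0.29, noise_sd = 0.003,
                         lag_time = 30, temperature = 298.15,
                         monomer_mass = 32200, seed = 1) {
  if (any(c(v_max, K_M, substrate_conc_0, enzyme_conc) < 0))
    stop("concentrations and rates must be non-negative")
  if (epsilon_275 <= 0) stop("epsilon_275 must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(as.list(environment()), class = "assay_params")
}

#' Simulate a photometric assay trace
#'
#' Integrates Michaelis-Menten substrate depletion
#' d\[S\]/dt = -v_max E \[S\]/(K_M + \[S\]) (E the enzyme mass concentration in
#' mg/ml, giving uM/s) after the lag phase and emits
#' A(t) = epsilon l \[S\](t) + Gaussian noise. Reproducible under the
#' parameter seed.
#'
#' @param params an [assay_params()].
#' @param duration total trace length, s (must exceed the lag).
#' @param dt sampling interval, s.
#' @return object of class `assay_trace`: `data` (time_s, A275),
#'   `metadata` and `truth` (the exact initial velocity used).
#' @export
simulate_assay_trace <- function(params, duration = 1200, dt = 2) {
  stopifnot(inherits(params, "assay_params"))
  if (dt <= 0) stop("dt must be positive")
  if (duration <= params$lag_time) stop("duration must exceed lag_time")
  e_mgml <- params$enzyme_conc * 1e-9 * 2 * params$monomer_mass  # g/L = mg/ml
  vmax_uMs <- params$v_max * e_mgml
  times <- seq(0, duration, by = dt)
  S <- numeric(length(times))
  pre <- times <= params$lag_time
  S[pre] <- params$substrate_conc_0
  if (any(!pre)) {
    tt <- c(params$lag_time, times[!pre])
    sol <- deSolve::ode(
      y = c(S = params$substrate_conc_0), times = tt,
      func = function(t, y, p) list(-vmax_uMs * y[1] / (params$K_M + y[1])),
      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-10)
    S[!pre] <- pmax(sol[-1, "S"], 0)
  }
  A <- params$epsilon_275 * params$path_length * S * 1e-6
  set.seed(params$seed)
  A <- A + stats::rnorm(length(A), sd = params$noise_sd)
  v0 <- vmax_uMs * params$substrate_conc_0 /
    (params$K_M + params$substrate_conc_0)
  structure(list(
    data = data.frame(time_s = times, A275 = A),
    metadata = list(substrate_uM = params$substrate_conc_0,
                    enzyme_nM = params$enzyme_conc,
                    enzyme_mg_ml = e_mgml, lag_time = params$lag_time),
    truth = list(v0_uM_s = v0, v0_specific = v0 / e_mgml,
                 vmax_uM_s = vmax_uMs),
    params = params), class = "assay_trace")
}

#' @export
print.assay_trace <- function(x, ...) {
  cat(sprintf("<assay_trace: %d points over %.0f s, S0 = %g uM, A0 = %.3f>\n",
              nrow(x$data), max(x$data$time_s), x$metadata$substrate_uM,
              x$data$A275[1]))
  invisible(x)
}

# pH from exact charge balance for a polyprotic analyte dissolved in its
# fully protonated form (charge z0, with inert counter-anions when z0 > 0,
# as for an amino-acid salt) and titrated with strong base. pkas
# ascending; concentrations mol/L.
.charge_balance_ph <- function(pkas, c_analyte, c_na, z0 = 0, Kw = 1e-14) {
  ka <- 10^(-pkas)
  cumka <- cumprod(ka)
  c_counter <- max(z0, 0) * c_analyte
  f <- function(pH) {
    h <- 10^(-pH)
    terms <- c(1, cumka / h^seq_along(cumka))
    alpha <- terms / sum(terms)              # fraction having lost j protons
    zbar <- z0 - sum(seq_along(cumka) * alpha[-1])
    c_na + h - Kw / h + c_analyte * zbar - c_counter
  }
  stats::uniroot(f, c(-2, 16), tol = 1e-12)$root
}

#' Simulate an acid/base titration
#'
#' Computes (added volume, pH) pairs from the exact multi-site charge
#' balance of a polyprotic analyte titrated with strong base, plus
#' Gaussian pH-reading noise.
#'
#' @param pka_list analyte pKa values, ascending.
#' @param analyte_conc analyte concentration, mM.
#' @param volume initial volume, ml.
#' @param titrant_conc strong-base (NaOH) concentration, mM.
#' @param noise_sd pH reading noise (default 0).
#' @param seed integer seed.
#' @param charge_fully_protonated charge of the fully protonated analyte
#'   (0 for a simple acid; +1 for an amino acid such as DHHA with one
#'   basic group).
#' @param n_points number of titrant additions.
#' @param titrant_excess added titrant as a multiple of the total
#'   equivalents (default 1.5).
#' @return data frame (volume_ml, pH).
#' @export
simulate_titration <- function(pka_list, analyte_conc = 10, volume = 75,
                               titrant_conc = 100, noise_sd = 0, seed = 1,
                               charge_fully_protonated = 0, n_points = 60,
                               titrant_excess = 1.5) {
  if (analyte_conc <= 0 || volume <= 0 || titrant_conc <= 0)
    stop("concentrations and volumes must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  pkas <- sort(as.numeric(pka_list))
  n_eq <- length(pkas) * analyte_conc * volume / titrant_conc
  v_add <- seq(0, titrant_excess * n_eq, length.out = n_points)
  pH <- vapply(v_add, function(v) {
    vt <- volume + v
    .charge_balance_ph(pkas, analyte_conc / 1000 * volume / vt,
                       titrant_conc / 1000 * v / vt,
                       z0 = charge_fully_protonated)
  }, numeric(1))
  if (noise_sd > 0) {
    set.seed(seed)
    pH <- pH + stats::rnorm(length(pH), sd = noise_sd)
  }
  data.frame(volume_ml = v_add, pH = pH)
}

#' Random coupled titratable system
#'
#' Generates a reproducible n-site system with intrinsic pKas uniform in
#' `pka_range` and symmetric positive couplings of magnitude
#' `coupling_scale` (half-normal), for exercising the titration engines.
#'
#' @param n_sites number of sites (>= 1).
#' @param pka_range length-2 range of intrinsic pKas.
#' @param coupling_scale kcal/mol scale of pairwise couplings; 0 gives
#'   independent sites.
#' @param seed integer seed.
#' @param temperature K.
#' @return a [titratable_system()].
#' @export
make_random_site_system <- function(n_sites, pka_range = c(2, 12),
                                    coupling_scale = 1, seed = 1,
                                    temperature = 298.15) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  set.seed(seed)
  pka <- stats::runif(n_sites, pka_range[1], pka_range[2])
  W <- matrix(0, n_sites, n_sites)
  if (coupling_scale > 0 && n_sites > 1) {
    for (i in 1:(n_sites - 1)) for (j in (i + 1):n_sites)
      W[i, j] <- W[j, i] <- abs(stats::rnorm(1)) * coupling_scale
  }
  titratable_system(
    data.frame(label = sprintf("site%02d", seq_len(n_sites)),
               pka = pka, charge_protonated = 0),
    W, temperature = temperature)
}
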