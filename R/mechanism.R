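#' Specify a mechanism's stationary points
#'
#' A `mechanism_spec` lists the stationary points of one reaction path as
#' alternating minima and maxima (first-order saddles), with energies in
#' kcal/mol relative to the first minimum, together with the harmonic
#' wavenumbers needed to build a two-dimensional surrogate surface: one
#' transverse (real) mode per stationary point and the reactive-mode
#' wavenumber that is lost at each saddle.
#'
#' @param name mechanism label, e.g. `"shuttle"`, `"sigmatropic"`,
#'   `"concerted"`, or `"taut_a"`/`"taut_b"`/`"taut_c"`.
#' @param labels character labels of the stationary points, in path order.
#' @param energies energies (kcal/mol) relative to the first minimum; must
#'   alternate minimum/maximum, starting and ending with a minimum (a
#'   single minimum is allowed), with the first equal to 0.
#' @param transverse_frequencies real transverse wavenumbers (cm^-1), one
#'   per stationary point (scalar recycled).
#' @param reactive_mode_frequency wavenumber (cm^-1) of the reactive mode
#'   at the minima; this mode turns imaginary at the saddles.
#' @return object of class `mechanism_spec`.
#' @export
mechanism_spec <- function(name, labels, energies,
                           transverse_frequencies = 1000,
                           reactive_mode_frequency = 2448) {
  energies <- as.numeric(energies)
  m <- length(energies)
  if (length(labels) != m) stop("labels and energies must have equal length")
  if (m < 1) stop("at least one stationary point is required")
  if (abs(energies[1]) > 1e-12)
    stop("energies must be relative to the first minimum (first energy 0)")
  if (m %% 2 == 0)
    stop("stationary points must start and end with a minimum (odd count)")
  if (m > 1) {
    d <- diff(energies)
    if (any(d == 0)) stop("adjacent stationary energies must differ")
    # odd segments ascend into a maximum, even segments descend from it
    expected <- rep(c(1, -1), length.out = m - 1)
    if (any(sign(d) != expected))
      stop("energies must alternate minimum/maximum along the path")
  }
  tf <- rep_len(as.numeric(transverse_frequencies), m)
  if (any(tf <= 0) || reactive_mode_frequency <= 0)
    stop("wavenumbers must be positive")
  structure(list(name = name, labels = as.character(labels),
                 energies = energies, transverse_frequencies = tf,
                 reactive_mode_frequency = as.numeric(reactive_mode_frequency)),
            class = "mechanism_spec")
}

#' @export
print.mechanism_spec <- function(x, ...) {
  kind <- rep(c("min", "TS"), length.out = length(x$energies))
  cat(sprintf("<mechanism_spec '%s'>\n", x$name))
  for (i in seq_along(x$energies))
    cat(sprintf("  %-4s %-28s %8.3f kcal/mol\n", kind[i], x$labels[i],
                x$energies[i]))
  invisible(x)
}

# Piecewise construction of the 1-D backbone V1(xi).
#
# On each inter-node segment the *derivative* is the cubic
#   d(u) = sgn * u (L - u) (p + q u),    p = S_left / L,  p + q L = S_right / L,
# which vanishes with prescribed curvature +/-S at both nodes and has no
# interior zero (p + q u > 0 on [0, L]); the segment length
#   L = sqrt(12 |dE| / (S_left + S_right))
# makes the integral of d equal the energy difference exactly. V1 is thus
# C2, has stationary points exactly at the nodes with the prescribed
# energies and curvatures, and is strictly monotone in between.
.mech_backbone <- function(energies, curvatures) {
  m <- length(energies)
  if (m == 1) {
    S0 <- curvatures[1]
    return(list(nodes = 0,
                value = function(xi) energies[1] + S0 * xi^2 / 2,
                deriv = function(xi) S0 * xi,
                deriv2 = function(xi) S0))
  }
  dE <- diff(energies)
  L <- sqrt(12 * abs(dE) / (curvatures[-m] + curvatures[-1]))
  nodes <- c(0, cumsum(L))
  p <- curvatures[-m] / L
  q <- (curvatures[-1] - curvatures[-m]) / L^2
  sgn <- sign(dE)
  Sfirst <- curvatures[1]; Slast <- curvatures[m]
  Efirst <- energies[1]; Elast <- energies[m]
  xmax <- nodes[m]
  seg_of <- function(xi) min(max(findInterval(xi, nodes), 1L), m - 1L)
  value <- function(xi) {
    if (xi <= 0) return(Efirst + Sfirst * xi^2 / 2)
    if (xi >= xmax) return(Elast + Slast * (xi - xmax)^2 / 2)
    i <- seg_of(xi); u <- xi - nodes[i]; Li <- L[i]
    energies[i] + sgn[i] * (p[i] * (Li * u^2 / 2 - u^3 / 3) +
                              q[i] * (Li * u^3 / 3 - u^4 / 4))
  }
  deriv <- function(xi) {
    if (xi <= 0) return(Sfirst * xi)
    if (xi >= xmax) return(Slast * (xi - xmax))
    i <- seg_of(xi); u <- xi - nodes[i]; Li <- L[i]
    sgn[i] * u * (Li - u) * (p[i] + q[i] * u)
  }
  deriv2 <- function(xi) {
    if (xi <= 0) return(Sfirst)
    if (xi >= xmax) return(Slast)
    i <- seg_of(xi); u <- xi - nodes[i]; Li <- L[i]
    sgn[i] * ((Li - 2 * u) * (p[i] + q[i] * u) + q[i] * u * (Li - u))
  }
  list(nodes = nodes, value = value, deriv = deriv, deriv2 = deriv2)
}

#' Build a 2-D surrogate surface from a mechanism spec
#'
#' Constructs V(xi, y) = V1(xi) + k(xi) y^2 / 2 whose stationary points lie
#' on the xi axis at the spec's energies (exactly, up to floating point),
#' whose reactive-mode curvature at every stationary point corresponds to
#' `reactive_mode_frequency` (positive at minima, negative at saddles) and
#' whose transverse frequency matches the spec at every stationary point.
#'
#' @param spec a [mechanism_spec()].
#' @param masses effective masses (amu) of the reaction coordinate and the
#'   transverse coordinate; default c(1, 1).
#' @return an [energy_surface()]; `info$stationary` holds the constructed
#'   stationary points (coordinates, energies, min/saddle kind).
#' @export
make_mechanism_surface <- function(spec, masses = c(1, 1)) {
  if (!inherits(spec, "mechanism_spec"))
    stop("spec must be a mechanism_spec")
  cf <- .const$freq_conv
  m <- length(spec$energies)
  # |curvature| giving the reactive-mode wavenumber at the surface masses
  S <- rep(masses[1] * (spec$reactive_mode_frequency / cf)^2, m)
  bb <- .mech_backbone(spec$energies, S)
  kT <- masses[2] * (spec$transverse_frequencies / cf)^2
  nodes <- bb$nodes
  kfun <- function(xi) {
    if (m == 1 || xi <= 0) return(kT[1])
    if (xi >= nodes[m]) return(kT[m])
    i <- min(max(findInterval(xi, nodes), 1L), m - 1L)
    t <- (xi - nodes[i]) / (nodes[i + 1] - nodes[i])
    kT[i] + (kT[i + 1] - kT[i]) * (3 * t^2 - 2 * t^3)
  }
  kderiv <- function(xi) {
    if (m == 1 || xi <= 0 || xi >= nodes[m]) return(0)
    i <- min(max(findInterval(xi, nodes), 1L), m - 1L)
    L <- nodes[i + 1] - nodes[i]
    t <- (xi - nodes[i]) / L
    (kT[i + 1] - kT[i]) * 6 * t * (1 - t) / L
  }
  kind <- rep(c("minimum", "saddle"), length.out = m)
  stationary <- lapply(seq_len(m), function(j)
    list(label = spec$labels[j], x = c(nodes[j], 0),
         energy = spec$energies[j], kind = kind[j]))
  energy_surface(
    2L,
    energy = function(x) bb$value(x[1]) + kfun(x[1]) * x[2]^2 / 2,
    gradient = function(x) c(bb$deriv(x[1]) + kderiv(x[1]) * x[2]^2 / 2,
                             kfun(x[1]) * x[2]),
    masses = masses,
    name = paste0("mechanism:", spec$name),
    info = list(spec = spec, stationary = stationary,
                minima = stationary[kind == "minimum"],
                saddles = stationary[kind == "saddle"]))
}

#' Canonical PhzF mechanism specs
#'
#' The shipped `"phzf"` catalogue encodes, as surrogate-surface stationary
#' energies, the candidate paths for the \[1,5\]-proton shift of DHHA: a
#' concerted sigmatropic shift (barrier 32.5 kcal/mol), a concerted
#' transfer through a cationic transition state (27.2 kcal/mol) and the
#' stepwise glutamate proton shuttle (step-1 barrier 14.3 kcal/mol after
#' zero-point correction). Only literature-anchored barrier values are
#' encoded; energies of unconstrained intermediates are free parameters with
#' the defaults below.
#'
#' @param name one of `"shuttle"`, `"sigmatropic"`, `"concerted"`.
#' @param intermediate_energy energy (kcal/mol) of the post-barrier
#'   minimum. For `"shuttle"` this is the high-lying C3-deprotonated
#'   intermediate (default 8, a free parameter); for the concerted paths it
#'   is the enol product level (default -11.5).
#' @param ... passed to [mechanism_spec()] (e.g. frequencies).
#' @return a [mechanism_spec()].
#' @export
phzf_surface_spec <- function(name = c("shuttle", "sigmatropic", "concerted"),
                              intermediate_energy = NULL, ...) {
  name <- match.arg(name)
  barrier <- switch(name, shuttle = 14.3, sigmatropic = 32.5,
                    concerted = 27.2)
  inter <- if (!is.null(intermediate_energy)) intermediate_energy
           else if (name == "shuttle") 8 else -11.5
  if (inter >= barrier)
    stop("intermediate_energy must lie below the barrier")
  labels <- switch(name,
    shuttle = c("E.DHHA", "TS C3 deprotonation", "C3-deprotonated intermediate"),
    sigmatropic = c("E.DHHA", "TS sigmatropic [1,5]-shift", "E.AHCDC"),
    concerted = c("E.DHHA", "TS cationic concerted", "E.AHCDC"))
  mechanism_spec(name, labels, c(0, barrier, inter), ...)
}
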