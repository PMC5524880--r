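#' Construct an energy surface
#'
#' An `energy_surface` is a differentiable scalar energy (kcal/mol) over
#' `dimension` abstract coordinates, the surrogate for a QM/MM potential.
#' When no analytic gradient is supplied, a central finite difference with
#' step 1e-5 is used.
#'
#' @param dimension positive integer, number of coordinates.
#' @param energy function of a numeric vector of length `dimension`
#'   returning a single finite energy in kcal/mol.
#' @param gradient optional function returning the analytic gradient
#'   (kcal/mol per coordinate unit); `NULL` for finite differences.
#' @param masses per-coordinate effective masses in amu (default all 1).
#' @param name descriptive label.
#' @param info optional list of metadata (e.g. known stationary points).
#' @return object of class `energy_surface`.
#' @export
energy_surface <- function(dimension, energy, gradient = NULL,
                           masses = rep(1, dimension), name = "surface",
                           info = list()) {
  stopifnot(is.function(energy), dimension >= 1,
            length(masses) == dimension, all(masses > 0))
  surf <- structure(
    list(dimension = as.integer(dimension), energy = energy,
         gradient = gradient, masses = as.numeric(masses),
         name = name, info = info),
    class = "energy_surface")
  surf
}

#' @export
print.energy_surface <- function(x, ...) {
  cat(sprintf("<energy_surface '%s': %d coordinate(s), %s gradient>\n",
              x$name, x$dimension,
              if (is.null(x$gradient)) "finite-difference" else "analytic"))
  invisible(x)
}

#' Evaluate surface energy
#' @param surface an `energy_surface`.
#' @param x coordinate vector.
#' @return energy in kcal/mol.
#' @export
surface_energy <- function(surface, x) {
  e <- surface$energy(as.numeric(x))
  if (!is.finite(e)) stop("surface energy is not finite at the given point")
  e
}

#' Evaluate surface gradient
#'
#' Uses the analytic gradient when the surface carries one, otherwise a
#' central finite difference with step `h`.
#'
#' @inheritParams surface_energy
#' @param h finite-difference step (default 1e-5 coordinate units).
#' @return gradient vector, kcal/mol per coordinate unit.
#' @export
surface_gradient <- function(surface, x, h = 1e-5) {
  x <- as.numeric(x)
  if (!is.null(surface$gradient)) return(as.numeric(surface$gradient(x)))
  g <- numeric(surface$dimension)
  for (i in seq_len(surface$dimension)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    g[i] <- (surface$energy(xp) - surface$energy(xm)) / (2 * h)
  }
  g
}

#' Central finite-difference Hessian of a surface
#'
#' @inheritParams surface_energy
#' @param h step size (default 1e-4 coordinate units).
#' @return symmetric dimension x dimension matrix, kcal/mol per unit^2.
#' @export
surface_hessian <- function(surface, x, h = 1e-4) {
  x <- as.numeric(x)
  n <- surface$dimension
  H <- matrix(0, n, n)
  e0 <- surface$energy(x)
  for (i in seq_len(n)) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h; xm[i] <- x[i] - h
    H[i, i] <- (surface$energy(xp) + surface$energy(xm) - 2 * e0) / h^2
    if (i < n) for (j in seq((i + 1), n)) {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[c(i, j)] <- x[c(i, j)] + h
      xmm[c(i, j)] <- x[c(i, j)] - h
      xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
      xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
      H[i, j] <- H[j, i] <-
        (surface$energy(xpp) - surface$energy(xpm) -
           surface$energy(xmp) + surface$energy(xmm)) / (4 * h^2)
    }
  }
  H
}

#' Catalogue of analytic test surfaces
#'
#' Closed-form surfaces with known stationary points, used to exercise the
#' path-optimization machinery:
#' \describe{
#'   \item{`quadratic_bowl`}{E = sum(k_i x_i^2)/2; single minimum at the
#'     origin. Params: `k` (vector or scalar, default 1), `dimension`
#'     (default 2).}
#'   \item{`double_well_1d`}{E(x) = (x^2-1)^2; minima at x = +/-1 (E = 0),
#'     saddle (maximum) at x = 0 with E = 1.}
#'   \item{`double_well_2d`}{E(x,y) = (x^2-1)^2 + k y^2 / 2; minima at
#'     (+/-1, 0), first-order saddle at (0,0) with E = 1. Params: `k`
#'     (default 2).}
#' }
#'
#' @param name one of `"quadratic_bowl"`, `"double_well_1d"`,
#'   `"double_well_2d"`.
#' @param params named list of numeric parameters (see above).
#' @return an [energy_surface()] with analytic gradient; `info$minima` and
#'   `info$saddles` list the exact stationary points.
#' @export
make_analytic_surface <- function(name, params = list()) {
  catalogue <- c("quadratic_bowl", "double_well_1d", "double_well_2d")
  if (!is.character(name) || length(name) != 1 || !(name %in% catalogue))
    stop("unknown surface name; valid names: ",
         paste(catalogue, collapse = ", "))
  switch(name,
    quadratic_bowl = {
      dim <- if (!is.null(params$dimension)) as.integer(params$dimension) else 2L
      k <- if (!is.null(params$k)) rep_len(as.numeric(params$k), dim) else rep(1, dim)
      energy_surface(
        dim,
        energy = function(x) sum(k * x^2) / 2,
        gradient = function(x) k * x,
        name = "quadratic_bowl",
        info = list(minima = list(list(x = rep(0, dim), energy = 0)),
                    saddles = list()))
    },
    double_well_1d = {
      energy_surface(
        1L,
        energy = function(x) (x[1]^2 - 1)^2,
        gradient = function(x) 4 * x[1] * (x[1]^2 - 1),
        name = "double_well_1d",
        info = list(minima = list(list(x = -1, energy = 0),
                                  list(x = 1, energy = 0)),
                    saddles = list(list(x = 0, energy = 1))))
    },
    double_well_2d = {
      k <- if (!is.null(params$k)) as.numeric(params$k) else 2
      energy_surface(
        2L,
        energy = function(x) (x[1]^2 - 1)^2 + k * x[2]^2 / 2,
        gradient = function(x) c(4 * x[1] * (x[1]^2 - 1), k * x[2]),
        name = "double_well_2d",
        info = list(minima = list(list(x = c(-1, 0), energy = 0),
                                  list(x = c(1, 0), energy = 0)),
                    saddles = list(list(x = c(0, 0), energy = 1))))
    })
}
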