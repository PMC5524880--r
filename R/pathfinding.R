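#' Reaction path object
#'
#' Ordered coordinate frames with their surface energies.
#'
#' @param surface an [energy_surface()].
#' @param frames numeric matrix (frames x coordinates) or vector for 1-D.
#' @param flags optional logical vector marking frames whose constrained
#'   minimization failed.
#' @return object of class `reaction_path` with elements `frames`
#'   (matrix), `energies` (kcal/mol) and `flags`.
#' @export
reaction_path <- function(surface, frames, flags = NULL) {
  if (is.null(dim(frames))) frames <- matrix(frames, ncol = surface$dimension)
  frames <- as.matrix(frames)
  dimnames(frames) <- NULL
  if (nrow(frames) < 2) stop("a path needs at least 2 frames")
  energies <- apply(frames, 1, function(x) surface_energy(surface, x))
  structure(list(frames = frames, energies = as.numeric(energies),
                 flags = if (is.null(flags)) rep(FALSE, nrow(frames)) else flags,
                 surface_name = surface$name),
            class = "reaction_path")
}

#' @export
print.reaction_path <- function(x, ...) {
  cat(sprintf("<reaction_path: %d frames on '%s', E range [%.4f, %.4f]>\n",
              nrow(x$frames), x$surface_name, min(x$energies), max(x$energies)))
  invisible(x)
}

.grad_norm <- function(surface, x) sqrt(sum(surface_gradient(surface, x)^2))

# Newton polish towards the nearest stationary point (any order).
.newton_polish <- function(surface, x, tolerance, max_iter = 60,
                           max_step = 0.25) {
  for (i in seq_len(max_iter)) {
    g <- surface_gradient(surface, x)
    if (sqrt(sum(g^2)) < tolerance) return(list(x = x, converged = TRUE))
    H <- surface_hessian(surface, x)
    step <- tryCatch(-solve(H, g), error = function(e) -g)
    sn <- sqrt(sum(step^2))
    if (sn > max_step) step <- step * (max_step / sn)
    x <- x + step
  }
  list(x = x, converged = sqrt(sum(surface_gradient(surface, x)^2)) < tolerance)
}

#' Classify a stationary point
#'
#' Computes the central-finite-difference Hessian (step `h`), mass-weights
#' it with the surface (or supplied) masses, and reports the eigenvalues,
#' the order (number of eigenvalues below -1e-8, absorbing round-off) and
#' the harmonic wavenumbers; negative eigenvalues yield imaginary
#' frequencies, flagged in the output.
#'
#' @param surface an [energy_surface()].
#' @param x coordinates of the candidate stationary point.
#' @param masses masses (amu) used for mass-weighting; defaults to the
#'   surface masses.
#' @param grad_tol maximum allowed gradient norm; larger gradients raise a
#'   "not stationary" error.
#' @param h Hessian finite-difference step (default 1e-4).
#' @return object of class `stationary_point`: coordinates, energy,
#'   `hessian_eigenvalues` (mass-weighted), `order`, and a `frequencies`
#'   data frame (wavenumber cm^-1, imaginary flag).
#' @export
classify_stationary <- function(surface, x, masses = NULL,
                                grad_tol = 1e-3, h = 1e-4) {
  x <- as.numeric(x)
  gn <- .grad_norm(surface, x)
  if (gn >= grad_tol)
    stop(sprintf("not stationary: gradient norm %.3e >= %.1e", gn, grad_tol))
  if (is.null(masses)) masses <- surface$masses
  H <- surface_hessian(surface, x, h = h)
  w <- 1 / sqrt(masses)
  Hmw <- H * outer(w, w)
  ev <- sort(eigen(Hmw, symmetric = TRUE, only.values = TRUE)$values)
  neg <- ev < -1e-8
  freq <- data.frame(wavenumber = .const$freq_conv * sqrt(abs(ev)),
                     imaginary = neg)
  structure(list(coordinates = x, energy = surface_energy(surface, x),
                 hessian_eigenvalues = ev, order = sum(neg),
                 frequencies = freq, grad_norm = gn),
            class = "stationary_point")
}

#' @export
print.stationary_point <- function(x, ...) {
  kind <- switch(as.character(x$order), "0" = "minimum",
                 "1" = "first-order saddle",
                 sprintf("order-%d saddle", x$order))
  cat(sprintf("<stationary_point: %s, E = %.6f kcal/mol, |grad| = %.2e>\n",
              kind, x$energy, x$grad_norm))
  invisible(x)
}

#' Minimize an energy surface
#'
#' BFGS descent followed by a Newton polish until the gradient norm falls
#' below `tolerance`; the result is classified via its Hessian.
#'
#' @param surface an [energy_surface()].
#' @param start starting coordinates.
#' @param tolerance gradient-norm convergence threshold (kcal/mol per
#'   coordinate unit).
#' @param max_iter maximum BFGS iterations.
#' @return a [classify_stationary()] result (order reported from the
#'   Hessian).
#' @export
minimize <- function(surface, start, tolerance = 1e-8, max_iter = 500) {
  start <- as.numeric(start)
  opt <- stats::optim(start, fn = function(x) surface_energy(surface, x),
                      gr = function(x) surface_gradient(surface, x),
                      method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  pol <- .newton_polish(surface, opt$par, tolerance)
  if (!pol$converged)
    stop(sprintf("minimization did not converge: last gradient norm %.3e",
                 .grad_norm(surface, pol$x)))
  classify_stationary(surface, pol$x, grad_tol = max(tolerance * 10, 1e-6))
}

#' Scan an initial reaction path along one coordinate
#'
#' At each value of the scanned coordinate the remaining coordinates are
#' relaxed (constrained minimization), giving a first estimate of the
#' reaction coordinate. Frames whose relaxation fails are flagged but the
#' path is still returned.
#'
#' @param surface an [energy_surface()].
#' @param coordinate_index index of the coordinate to scan.
#' @param range length-2 numeric, scan range.
#' @param n_points number of scan values (>= 3).
#' @param start starting values for the relaxed coordinates.
#' @return a [reaction_path()] ordered by scan value.
#' @export
scan_initial_path <- function(surface, coordinate_index, range, n_points,
                              start = rep(0, surface$dimension)) {
  if (n_points < 3) stop("n_points must be >= 3")
  vals <- seq(range[1], range[2], length.out = n_points)
  n <- surface$dimension
  rest <- setdiff(seq_len(n), coordinate_index)
  frames <- matrix(0, n_points, n)
  flags <- rep(FALSE, n_points)
  guess <- as.numeric(start)[rest]
  for (i in seq_along(vals)) {
    if (length(rest) == 0) {
      frames[i, ] <- vals[i]
      next
    }
    fn <- function(z) {
      x <- numeric(n); x[coordinate_index] <- vals[i]; x[rest] <- z
      surface_energy(surface, x)
    }
    gr <- function(z) {
      x <- numeric(n); x[coordinate_index] <- vals[i]; x[rest] <- z
      surface_gradient(surface, x)[rest]
    }
    opt <- tryCatch(
      stats::optim(guess, fn, gr, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) {
      flags[i] <- TRUE
      z <- guess
    } else {
      z <- opt$par
      guess <- z          # continuation: warm-start the next scan value
    }
    frames[i, coordinate_index] <- vals[i]
    frames[i, rest] <- z
  }
  reaction_path(surface, frames, flags = flags)
}

# Improved-tangent estimate (upwind in energy) for image i.
.neb_tangent <- function(frames, energies, i) {
  tp <- frames[i + 1, ] - frames[i, ]
  tm <- frames[i, ] - frames[i - 1, ]
  ep <- energies[i + 1]; e0 <- energies[i]; em <- energies[i - 1]
  if (ep > e0 && e0 > em) tau <- tp
  else if (ep < e0 && e0 < em) tau <- tm
  else {
    dmax <- max(abs(ep - e0), abs(em - e0))
    dmin <- min(abs(ep - e0), abs(em - e0))
    tau <- if (ep > em) tp * dmax + tm * dmin else tp * dmin + tm * dmax
  }
  tau / sqrt(sum(tau^2))
}

#' Nudged-elastic-band path refinement
#'
#' Standard NEB with the improved-tangent rule, optional climbing image and
#' a FIRE optimizer. Endpoints are held fixed and must be minima.
#' Convergence requires the perpendicular true force (and, with climbing,
#' the full force on the climbing image) below `tolerance` on all interior
#' images.
#'
#' @param surface an [energy_surface()].
#' @param path a [reaction_path()] with >= 3 frames whose endpoints are
#'   minima.
#' @param spring_constant inter-image spring constant, kcal/mol/unit^2
#'   (default 1).
#' @param climbing logical; drive the highest image uphill along the
#'   tangent towards the saddle (default TRUE).
#' @param tolerance force convergence threshold (default 1e-4).
#' @param max_iter maximum optimizer iterations (default 5000); when
#'   exceeded, the partial path is returned with a convergence report.
#' @return a [reaction_path()] with attribute `"convergence"` (list:
#'   converged, iterations, max_force, climbing_index).
#' @export
neb_refine <- function(surface, path, spring_constant = 1, climbing = TRUE,
                       tolerance = 1e-4, max_iter = 5000) {
  frames <- path$frames
  n_img <- nrow(frames)
  if (n_img < 3) stop("NEB needs at least 3 frames")
  for (e in c(1, n_img))
    if (.grad_norm(surface, frames[e, ]) > 1e-3)
      stop("NEB endpoints must be minima (gradient too large at an endpoint)")
  n <- ncol(frames)
  vel <- matrix(0, n_img, n)
  dt <- 0.02; dt_max <- 0.2; alpha <- 0.1; n_pos <- 0L
  f_inc <- 1.1; f_dec <- 0.5; alpha0 <- 0.1; f_alpha <- 0.99; n_min <- 5L
  max_disp <- 0.1
  energies <- apply(frames, 1, function(x) surface_energy(surface, x))
  climb_idx <- NA_integer_
  forces <- matrix(0, n_img, n)
  max_force <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    grads <- matrix(0, n_img, n)
    for (i in seq_len(n_img))
      grads[i, ] <- surface_gradient(surface, frames[i, ])
    if (climbing) climb_idx <- 1L + which.max(energies[2:(n_img - 1)])
    max_force <- 0
    for (i in 2:(n_img - 1)) {
      tau <- .neb_tangent(frames, energies, i)
      g <- grads[i, ]
      g_par <- sum(g * tau)
      if (climbing && i == climb_idx) {
        f <- -g + 2 * g_par * tau
        fnrm <- sqrt(sum(f^2))
      } else {
        f_perp <- -(g - g_par * tau)
        dplus <- sqrt(sum((frames[i + 1, ] - frames[i, ])^2))
        dminus <- sqrt(sum((frames[i, ] - frames[i - 1, ])^2))
        f <- f_perp + spring_constant * (dplus - dminus) * tau
        fnrm <- sqrt(sum(f_perp^2))
      }
      forces[i, ] <- f
      max_force <- max(max_force, fnrm)
    }
    if (max_force < tolerance) break
    # FIRE update on interior images
    idx <- 2:(n_img - 1)
    P <- sum(vel[idx, ] * forces[idx, ])
    if (P > 0) {
      n_pos <- n_pos + 1L
      vnrm <- sqrt(sum(vel[idx, ]^2)); fnrm <- sqrt(sum(forces[idx, ]^2))
      if (fnrm > 0)
        vel[idx, ] <- (1 - alpha) * vel[idx, ] +
          alpha * forces[idx, ] * (vnrm / fnrm)
      if (n_pos > n_min) { dt <- min(dt * f_inc, dt_max); alpha <- alpha * f_alpha }
    } else {
      vel[idx, ] <- 0; dt <- dt * f_dec; alpha <- alpha0; n_pos <- 0L
    }
    vel[idx, ] <- vel[idx, ] + dt * forces[idx, ]
    disp <- dt * vel[idx, ]
    dn <- sqrt(rowSums(matrix(disp^2, ncol = n)))
    scale <- pmin(1, max_disp / pmax(dn, 1e-300))
    frames[idx, ] <- frames[idx, ] + disp * scale
    energies[idx] <- apply(frames[idx, , drop = FALSE], 1,
                           function(x) surface_energy(surface, x))
  }
  out <- reaction_path(surface, frames)
  attr(out, "convergence") <- list(converged = max_force < tolerance,
                                   iterations = iter, max_force = max_force,
                                   climbing_index = climb_idx)
  if (max_force >= tolerance)
    warning(sprintf("NEB did not converge in %d iterations (max force %.2e)",
                    max_iter, max_force))
  out
}

# One saddle refinement: maximize along the (fixed) path tangent, minimize
# in the conjugate (orthogonal) subspace, iterate, then Newton-polish.
.cpr_refine_peak <- function(surface, x0, tau, tolerance, max_cycles,
                             bracket = 0.5) {
  n <- surface$dimension
  tau <- tau / sqrt(sum(tau^2))
  x <- as.numeric(x0)
  for (cycle in seq_len(max_cycles)) {
    lm <- stats::optimize(function(s) -surface_energy(surface, x + s * tau),
                          interval = c(-bracket, bracket))
    x <- x + lm$minimum * tau
    if (n > 1) {
      B <- qr.Q(qr(cbind(tau, diag(n))))[, -1, drop = FALSE]
      fn <- function(z) surface_energy(surface, x + B %*% z)
      gr <- function(z) as.numeric(t(B) %*% surface_gradient(surface, x + B %*% z))
      opt <- stats::optim(rep(0, n - 1), fn, gr, method = "BFGS",
                          control = list(maxit = 200, reltol = 1e-14))
      x <- as.numeric(x + B %*% opt$par)
    }
    if (.grad_norm(surface, x) < 100 * tolerance) break
  }
  pol <- .newton_polish(surface, x, tolerance)
  pol$x
}

#' Conjugate-peak-refinement of a reaction path
#'
#' Locates the interior energy maxima of a piecewise-linear path, refines
#' each by alternating maximization along the local path tangent with
#' minimization in the conjugate (orthogonal) subspace, polishes with
#' Newton steps, and classifies the result. Refined peaks of order >= 2
#' are flagged as higher-order saddles rather than silently accepted.
#'
#' @param surface an [energy_surface()].
#' @param path a [reaction_path()] whose endpoints are minima.
#' @param tolerance gradient-norm threshold for a refined saddle
#'   (default 1e-8).
#' @param max_cycles tangent-maximization/conjugate-minimization cycles
#'   per peak (default 30).
#' @return list with `path` (the input path with refined saddle frames
#'   spliced in) and `saddles` (list of [classify_stationary()] results,
#'   each with a `higher_order` flag).
#' @export
cpr_refine <- function(surface, path, tolerance = 1e-8, max_cycles = 30) {
  frames <- path$frames
  energies <- path$energies
  n_img <- nrow(frames)
  for (e in c(1, n_img))
    if (.grad_norm(surface, frames[e, ]) > 1e-3)
      stop("CPR endpoints must be minima")
  interior <- which(diff(sign(diff(energies))) == -2) + 1L
  interior <- interior[interior > 1 & interior < n_img]
  saddles <- list()
  new_frames <- frames
  for (i in interior) {
    tau <- frames[min(i + 1, n_img), ] - frames[max(i - 1, 1), ]
    seg <- sqrt(sum(tau^2))
    xs <- .cpr_refine_peak(surface, frames[i, ], tau, tolerance, max_cycles,
                           bracket = max(seg, 1e-2))
    sp <- classify_stationary(surface, xs, grad_tol = max(tolerance * 100, 1e-5))
    sp$higher_order <- sp$order >= 2
    if (sp$higher_order)
      warning(sprintf("refined peak at frame %d is a higher-order saddle (order %d)",
                      i, sp$order))
    saddles[[length(saddles) + 1]] <- sp
    new_frames[i, ] <- xs
  }
  list(path = reaction_path(surface, new_frames), saddles = saddles)
}

#' Barrier height
#'
#' Highest saddle (or interior path) energy minus the reactant energy;
#' returns 0 when the input contains no saddle or the path is monotone
#' downhill.
#'
#' @param x a [reaction_path()], a list of stationary points (or of lists
#'   with an `energy` element), or a numeric vector of saddle energies.
#' @param reactant_energy reference energy; defaults to the first frame
#'   energy for a path and 0 otherwise.
#' @return barrier in kcal/mol (>= 0).
#' @export
barrier <- function(x, reactant_energy = NULL) {
  if (inherits(x, "reaction_path")) {
    if (is.null(reactant_energy)) reactant_energy <- x$energies[1]
    n <- length(x$energies)
    if (n < 3) return(0)
    top <- max(x$energies[2:(n - 1)])
    return(max(0, top - reactant_energy))
  }
  if (is.null(reactant_energy)) reactant_energy <- 0
  if (is.list(x)) {
    if (length(x) == 0) return(0)
    en <- vapply(x, function(s) as.numeric(s$energy), numeric(1))
  } else {
    en <- as.numeric(x)
    if (length(en) == 0) return(0)
  }
  max(0, max(en) - reactant_energy)
}
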