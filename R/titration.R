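#' Multi-site titratable system
#'
#' Sites with intrinsic pKa values, charges of the protonated form, and a
#' symmetric pairwise interaction matrix W (kcal/mol) acting between
#' protonated forms. This is the surrogate for a continuum-electrostatics
#' site model.
#'
#' @param sites data frame with columns `label`, `pka`
#'   (intrinsic pKa), `charge_protonated`.
#' @param interaction symmetric numeric matrix (kcal/mol) with zero
#'   diagonal; default all zero (independent sites).
#' @param temperature K (default 298.15).
#' @return object of class `titratable_system`.
#' @export
titratable_system <- function(sites, interaction = NULL,
                              temperature = 298.15) {
  stopifnot(is.data.frame(sites), all(c("label", "pka") %in% names(sites)))
  n <- nrow(sites)
  if (is.null(sites$charge_protonated)) sites$charge_protonated <- 0
  if (!all(is.finite(sites$pka))) stop("pKa values must be finite")
  if (is.null(interaction)) interaction <- matrix(0, n, n)
  interaction <- as.matrix(interaction)
  if (!isTRUE(all.equal(interaction, t(interaction), tolerance = 1e-10)))
    stop("interaction matrix W must be symmetric")
  if (any(abs(diag(interaction)) > 1e-12))
    stop("interaction matrix W must have zero diagonal")
  if (nrow(interaction) != n) stop("interaction dimension mismatch")
  structure(list(sites = sites, interaction = interaction,
                 temperature = temperature, n_sites = n),
            class = "titratable_system")
}

#' @export
print.titratable_system <- function(x, ...) {
  cat(sprintf("<titratable_system: %d site(s), T = %.2f K, %s coupling>\n",
              x$n_sites, x$temperature,
              if (all(x$interaction == 0)) "no" else "pairwise"))
  invisible(x)
}

#' Free energy of a protonation microstate
#'
#' G(s; pH) = sum_i s_i ln(10) R T (pH - pKa_i) + sum_{i<j} W_ij s_i s_j,
#' relative to the fully deprotonated state.
#'
#' @param system a [titratable_system()].
#' @param s binary protonation vector (1 = protonated).
#' @param pH solution pH.
#' @return microstate free energy, kcal/mol.
#' @export
microstate_energy <- function(system, s, pH) {
  s <- as.numeric(s)
  if (length(s) != system$n_sites) stop("microstate length mismatch")
  if (!all(s %in% c(0, 1))) stop("s must be binary")
  RT <- .const$R_kcal * system$temperature
  sum(s * .const$ln10 * RT * (pH - system$sites$pka)) +
    sum(s * (system$interaction %*% s)) / 2
}

#' Exact titration curve by microstate enumeration
#'
#' Boltzmann-averages the per-site protonation probability over all 2^n
#' microstates at each grid pH. This is the brute-force oracle for the
#' Monte Carlo engine; it refuses systems with more than 20 sites.
#'
#' @param system a [titratable_system()].
#' @param pH_grid numeric grid (default 0 to 14 step 0.1).
#' @return object of class `titration_curve`: `pH`, `prob` (grid x sites
#'   matrix of mean protonation), `method = "exact"`.
#' @export
enumerate_titration <- function(system, pH_grid = seq(0, 14, by = 0.1)) {
  n <- system$n_sites
  if (n > 20)
    stop("exact enumeration is limited to 20 sites (2^n states); ",
         "use mc_titrate() for larger systems")
  S <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  colnames(S) <- system$sites$label
  RT <- .const$R_kcal * system$temperature
  pair <- rowSums((S %*% system$interaction) * S) / 2
  nprot <- rowSums(S)
  spk <- as.numeric(S %*% system$sites$pka)
  prob <- matrix(NA_real_, length(pH_grid), n)
  for (k in seq_along(pH_grid)) {
    G <- .const$ln10 * RT * (pH_grid[k] * nprot - spk) + pair
    w <- exp(-(G - min(G)) / RT)
    prob[k, ] <- as.numeric(t(S) %*% w) / sum(w)
  }
  colnames(prob) <- system$sites$label
  structure(list(pH = pH_grid, prob = prob, method = "exact",
                 labels = system$sites$label),
            class = "titration_curve")
}

#' Metropolis Monte Carlo titration
#'
#' Single-site-flip Metropolis sampling of the protonation microstate at
#' each grid pH, reproducible under the seed. One Monte Carlo step is one
#' systematic scan over all sites (each site attempted as a single flip),
#' the usual convention in multi-site titration samplers. Monte Carlo
#' standard errors are estimated per site by batch means (20 batches).
#'
#' @inheritParams enumerate_titration
#' @param n_steps Monte Carlo steps (full scans) per pH point
#'   (default 1e5).
#' @param burn_in discarded initial steps (default `n_steps %/% 10`).
#' @param seed integer seed.
#' @return a `titration_curve` with `method = "mc"`, `se` matrix,
#'   `n_steps` and `seed`.
#' @export
mc_titrate <- function(system, pH_grid = seq(0, 14, by = 0.1),
                       n_steps = 1e5, burn_in = n_steps %/% 10, seed = 1) {
  if (burn_in >= n_steps) stop("n_steps must exceed burn_in")
  set.seed(seed)
  RT <- .const$R_kcal * system$temperature
  res <- mc_titrate_kernel(system$sites$pka, system$interaction,
                           as.numeric(pH_grid), as.integer(n_steps),
                           as.integer(burn_in), RT, .const$ln10)
  prob <- res$prob; se <- res$se
  colnames(prob) <- colnames(se) <- system$sites$label
  structure(list(pH = as.numeric(pH_grid), prob = prob, se = se,
                 method = "mc", n_steps = n_steps, burn_in = burn_in,
                 seed = seed, labels = system$sites$label),
            class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve (%s): %d pH points (%.1f-%.1f), %d site(s)>\n",
              x$method, length(x$pH), min(x$pH), max(x$pH), ncol(x$prob)))
  invisible(x)
}

#' @export
as.data.frame.titration_curve <- function(x, ...) {
  data.frame(pH = x$pH, x$prob, check.names = FALSE)
}

#' Half-protonation pKa from a titration curve
#'
#' Linear interpolation of the crossings of protonation probability 0.5
#' for one site. When the curve crosses 0.5 several times (e.g. an
#' anticooperative pair), all crossings are returned and the first is
#' reported as `pka`.
#'
#' @param curve a `titration_curve`.
#' @param site site index or label.
#' @return list with `pka` (first crossing) and `crossings` (all).
#' @export
pka_half <- function(curve, site = 1) {
  if (is.character(site)) site <- match(site, curve$labels)
  p <- curve$prob[, site]
  d <- p - 0.5
  hit <- which(abs(d) < .Machine$double.eps)
  cross <- which(d[-length(d)] * d[-1] < 0)
  out <- sort(c(curve$pH[hit],
                vapply(cross, function(i) {
                  curve$pH[i] + (curve$pH[i + 1] - curve$pH[i]) *
                    d[i] / (d[i] - d[i + 1])
                }, numeric(1))))
  if (length(out) == 0)
    stop("site titrates outside the pH range: no 0.5 crossing in the grid")
  list(pka = out[1], crossings = out)
}

#' Convert between pKa units and free energy
#'
#' Deprotonation free energy at a given pH: dG = ln(10) R T (pKa - pH).
#' A pKa-unit gap (pH-independent difference) converts as
#' dG = ln(10) R T gap.
#'
#' @param value input value (kcal/mol or pKa units depending on
#'   `direction`).
#' @param direction one of `"pka_to_energy"`, `"energy_to_pka"`,
#'   `"gap_to_energy"`, `"energy_to_gap"`.
#' @param pH reference pH (required for the first two directions).
#' @param T temperature in K (default 298.15).
#' @return converted value.
#' @export
convert_pka_energy <- function(value,
                               direction = c("pka_to_energy", "energy_to_pka",
                                             "gap_to_energy", "energy_to_gap"),
                               pH = NULL, T = 298.15) {
  direction <- match.arg(direction)
  if (T <= 0) stop("temperature must be positive")
  slope <- .const$ln10 * .const$R_kcal * T
  switch(direction,
    pka_to_energy = {
      if (is.null(pH)) stop("pH is required for pka_to_energy")
      slope * (value - pH)
    },
    energy_to_pka = {
      if (is.null(pH)) stop("pH is required for energy_to_pka")
      pH + value / slope
    },
    gap_to_energy = slope * value,
    energy_to_gap = value / slope)
}

# Model pKa values (N-epsilon tautomer for His) used by
# build_sites_from_structure; TERMN/TERMC are chain termini.
.model_pkas_default <- data.frame(
  resid = c("ASP", "GLU", "HIS", "LYS", "ARG", "TYR", "CYS", "TERMN", "TERMC"),
  atom  = c("CG",  "CD",  "NE2", "NZ",  "CZ",  "OH",  "SG",  "N",     "C"),
  pka   = c(4.0,   4.4,   6.5,   10.4,  12.0,  9.6,   8.3,   8.0,     3.6),
  charge_protonated = c(0, 0, 1, 1, 1, 0, 0, 1, 0),
  stringsAsFactors = FALSE)

#' Build a titratable site model from a PDB structure
#'
#' One site per titratable residue (Asp, Glu, His, Lys, Arg, Tyr, Cys and,
#' optionally, chain termini). Pairwise interactions use a screened
#' Coulomb surrogate between the charges of the protonated forms at
#' representative charged-atom distances:
#' W_ij = 332.06 q_i q_j exp(-kappa r_ij) / (epsilon r_ij) kcal/mol.
#' Histidine is modeled as a single site in the N-epsilon tautomer.
#'
#' @param structure_file path to a standard PDB file.
#' @param effective_dielectric single effective dielectric constant
#'   (default 20).
#' @param ionic_strength mol/L; sets the Debye screening length
#'   kappa = sqrt(I)/3.04 per Angstrom at 298 K (default 0, no screening).
#' @param model_pkas table of model pKas per residue type (columns
#'   `resid`, `atom`, `pka`, `charge_protonated`); defaults to standard
#'   solution values with His at the N-epsilon position.
#' @param include_termini also create N-/C-terminal sites (default FALSE).
#' @param temperature K.
#' @return a [titratable_system()].
#' @export
build_sites_from_structure <- function(structure_file,
                                       effective_dielectric = 20,
                                       ionic_strength = 0,
                                       model_pkas = .model_pkas_default,
                                       include_termini = FALSE,
                                       temperature = 298.15) {
  if (!file.exists(structure_file)) stop("file not found: ", structure_file)
  lines <- readLines(structure_file, warn = FALSE)
  atom_lines <- grep("^(ATOM|HETATM)", lines)
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(ln, 31, 38)))))
      stop(sprintf("cannot parse PDB record at line %d: '%s'", i,
                   substr(ln, 1, 30)))
  }
  pdb <- tryCatch(bio3d::read.pdb(structure_file, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  keys <- unique(at[, c("chain", "resno", "resid")])
  rows <- list()
  for (r in seq_len(nrow(keys))) {
    resid <- keys$resid[r]
    m <- model_pkas[model_pkas$resid == resid & model_pkas$resid != "TERMN" &
                      model_pkas$resid != "TERMC", ]
    if (nrow(m) == 0) {
      if (resid %in% c("ALA", "GLY", "VAL", "LEU", "ILE", "PRO", "PHE",
                       "TRP", "MET", "SER", "THR", "ASN", "GLN", "HOH"))
        next
      warning("no model pKa for residue type ", resid, "; site skipped")
      next
    }
    sel <- at$chain == keys$chain[r] & at$resno == keys$resno[r] &
      at$elety == m$atom[1]
    if (!any(sel)) {
      warning(sprintf("representative atom %s missing for %s %s%d; skipped",
                      m$atom[1], resid, keys$chain[r], keys$resno[r]))
      next
    }
    j <- which(sel)[1]
    rows[[length(rows) + 1]] <- data.frame(
      label = sprintf("%s-%s%d", resid, keys$chain[r], keys$resno[r]),
      pka = m$pka[1], charge_protonated = m$charge_protonated[1],
      x = at$x[j], y = at$y[j], z = at$z[j], stringsAsFactors = FALSE)
  }
  if (include_termini) {
    for (ch in unique(at$chain)) {
      sub <- at[at$chain == ch & at$type == "ATOM", ]
      for (end in c("TERMN", "TERMC")) {
        m <- model_pkas[model_pkas$resid == end, ]
        if (nrow(m) == 0) next
        resno <- if (end == "TERMN") min(sub$resno) else max(sub$resno)
        j <- which(sub$resno == resno & sub$elety == m$atom[1])[1]
        if (is.na(j)) next
        rows[[length(rows) + 1]] <- data.frame(
          label = sprintf("%s-%s%d", end, ch, resno),
          pka = m$pka[1], charge_protonated = m$charge_protonated[1],
          x = sub$x[j], y = sub$y[j], z = sub$z[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) stop("no titratable sites detected")
  sites <- do.call(rbind, rows)
  n <- nrow(sites)
  W <- matrix(0, n, n)
  kappa <- sqrt(ionic_strength) / 3.04
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    rij <- sqrt(sum((unlist(sites[i, c("x", "y", "z")]) -
                       unlist(sites[j, c("x", "y", "z")]))^2))
    W[i, j] <- W[j, i] <-
      332.06 * sites$charge_protonated[i] * sites$charge_protonated[j] *
      exp(-kappa * rij) / (effective_dielectric * rij)
  }
  titratable_system(sites[, c("label", "pka", "charge_protonated")], W,
                    temperature = temperature)
}
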