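# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Brute-force saddle energy on a surface with a single reaction coordinate
# x: for each grid x, minimize over the remaining coordinate(s) by 1-D
# optimize (dimension <= 2 assumed), then take the maximum of the
# min-energy profile strictly between the two end minima.
grid_saddle_energy <- function(surface, x_range, step = 1e-3, y_range = c(-2, 2)) {
  xs <- seq(x_range[1], x_range[2], by = step)
  prof <- vapply(xs, function(x) {
    if (surface$dimension == 1) return(surface$energy(x))
    stats::optimize(function(y) surface$energy(c(x, y)),
                    interval = y_range)$objective
  }, numeric(1))
  # interior maximum of the minimum-energy profile
  interior <- 2:(length(xs) - 1)
  i <- interior[which.max(prof[interior])]
  list(x = xs[i], energy = prof[i])
}

# Hand-summed Boltzmann average over all microstates of a small system:
# explicit loops, explicit formula, no matrix algebra.
hand_titration_prob <- function(pka, W, pH, temperature = 298.15) {
  R <- 1.9872e-3; ln10 <- log(10)
  RT <- R * temperature
  n <- length(pka)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  G <- numeric(nrow(states))
  for (k in seq_len(nrow(states))) {
    s <- states[k, ]
    g <- 0
    for (i in seq_len(n)) {
      if (s[i] == 1) g <- g + ln10 * RT * (pH - pka[i])
      if (i < n) for (j in (i + 1):n)
        if (s[i] == 1 && s[j] == 1) g <- g + W[i, j]
    }
    G[k] <- g
  }
  w <- exp(-(G - min(G)) / RT)
  vapply(seq_len(n), function(i) sum(w[states[, i] == 1]) / sum(w),
         numeric(1))
}

# Starting pH of a polyprotic acid solution from the charge-balance
# polynomial in h = [H+], solved with polyroot (independent of the
# package's uniroot-on-pH route). Concentrations in mol/L.
polyroot_start_ph <- function(pkas, c_acid, z0 = 0, Kw = 1e-14) {
  ka <- 10^(-pkas)
  n <- length(ka)
  # charge balance: h - Kw/h + c_acid * zbar(h) = 0, with
  # zbar = z0 - sum_j j * beta_j / h^j / D, D = sum_j beta_j / h^j,
  # beta_j = prod_{k<=j} ka_k. Multiply by h^(n+1) * D(h)*h^n to get a
  # polynomial in h.
  beta <- c(1, cumprod(ka))          # beta_0 .. beta_n
  # descending-power coefficient vectors: position 1 <-> highest power.
  # D(h)*h^n = sum_j beta_j h^(n-j): coefficient of h^(n-j) at position j+1
  D <- beta
  # zbar-numerator * h^n = sum_j (z0 - j - z0_counter) beta_j h^(n-j),
  # including the inert counter-anions of the fully protonated salt
  Z <- (z0 - 0:n - max(z0, 0)) * beta
  pmul <- function(p, k) c(p, numeric(k))            # multiply by h^k
  padd <- function(a, b) {
    L <- max(length(a), length(b))
    c(numeric(L - length(a)), a) + c(numeric(L - length(b)), b)
  }
  # f(h) * h * D(h) h^n = h^2 D - Kw D + c_acid h Z
  poly <- padd(padd(pmul(D, 2), -Kw * D), c_acid * pmul(Z, 1))
  rts <- polyroot(rev(poly))          # polyroot wants ascending powers
  h <- Re(rts[abs(Im(rts)) < 1e-9 & Re(rts) > 0])
  h <- h[h > 1e-16 & h < 100]
  # the physical root satisfies the original (rational) charge balance
  resid <- vapply(h, function(hh) {
    terms <- c(1, cumprod(ka) / hh^seq_len(n))
    alpha <- terms / sum(terms)
    zbar <- z0 - sum((1:n) * alpha[-1])
    abs(hh - Kw / hh + c_acid * (zbar - max(z0, 0)))
  }, numeric(1))
  -log10(h[which.min(resid)])
}

# Build a noisy protiated/deuterated kinetics dataset at the canonical
# plate design (8 two-fold dilutions from 1000 uM, triplicate).
make_rate_table <- function(v_max, K_M, seed, enzyme_conc = 40,
                            noise_sd = 0.002) {
  concs <- 1000 / 2^(0:7)
  rows <- list(); k <- 0
  for (s in concs) for (r in 1:3) {
    k <- k + 1
    p <- assay_params(v_max = v_max, K_M = K_M, substrate_conc_0 = s,
                      enzyme_conc = enzyme_conc, noise_sd = noise_sd,
                      lag_time = 30, seed = seed + k)
    tr <- simulate_assay_trace(p, duration = 1200, dt = 5)
    rm <- extract_initial_rate(tr)
    rows[[k]] <- data.frame(substrate_conc = s, velocity = rm$velocity,
                            replicate = r)
  }
  do.call(rbind, rows)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "phzfmech", mustWork = TRUE)
}
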