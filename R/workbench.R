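#' Pipeline run configuration
#'
#' @param stages character vector of stages to execute, in order, from
#'   `c("synth", "pathfinding", "titration", "rates", "kinetics",
#'   "profile")`; empty for a no-op run.
#' @param out_dir output directory for tables and the run report; `NULL`
#'   keeps everything in memory.
#' @param seed master seed; stage seeds are derived from it and recorded
#'   in the report.
#' @param temperature K used by the rate calculators.
#' @param kie_temperature K used for the intrinsic-KIE conversion
#'   (default 288.15).
#' @param n_conc,n_rep substrate-dilution count and replicates of the
#'   simulated kinetics design.
#' @return list of class `run_config`.
#' @export
run_config <- function(stages = c("synth", "pathfinding", "titration",
                                  "rates", "kinetics", "profile"),
                       out_dir = NULL, seed = 1, temperature = 298.15,
                       kie_temperature = 288.15, n_conc = 8, n_rep = 3) {
  known <- c("synth", "pathfinding", "titration", "rates", "kinetics",
             "profile")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(stages = stages, out_dir = out_dir, seed = seed,
                 temperature = temperature,
                 kie_temperature = kie_temperature,
                 n_conc = n_conc, n_rep = n_rep),
            class = "run_config")
}

# Simulate one kinetics dataset (serial dilution, replicates) and extract
# initial rates. Returns the rate table.
.simulate_rate_table <- function(v_max, K_M, seed, n_conc = 8, n_rep = 3,
                                 enzyme_conc = 40, noise_sd = 0.002) {
  concs <- 1000 / 2^(seq_len(n_conc) - 1)
  rows <- list()
  k <- 0
  for (s in concs) for (r in seq_len(n_rep)) {
    k <- k + 1
    p <- assay_params(v_max = v_max, K_M = K_M, substrate_conc_0 = s,
                      enzyme_conc = enzyme_conc, noise_sd = noise_sd,
                      lag_time = 30, seed = seed + k)
    tr <- simulate_assay_trace(p, duration = 1200, dt = 5)
    rm <- extract_initial_rate(tr, epsilon = p$epsilon_275,
                               path_length = p$path_length)
    rows[[k]] <- data.frame(substrate_conc = s, velocity = rm$velocity,
                            replicate = r)
  }
  do.call(rbind, rows)
}

#' Run the canonical analysis pipeline
#'
#' Executes the requested stages on the shipped canonical configuration:
#' surrogate-surface construction and conjugate peak refinement of the
#' shuttle path, exact + Monte Carlo titration of the DHHA two-site model,
#' the KIE/TST calculators, a full simulated kinetics experiment for the
#' protiated and C3-deuterated substrate with Michaelis-Menten fits and
#' apparent KIEs, and catalytic-cycle profile assembly with mechanism
#' ranking. All randomness flows through seeds derived from the config
#' seed and is recorded in the report.
#'
#' @param config a [run_config()].
#' @return list of class `run_report` with one element per executed stage
#'   plus `seeds`, `versions` and `elapsed_s`; written as tables and a
#'   JSON report when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  report <- list(seeds = list(master = config$seed),
                 versions = list(
                   phzfmech = as.character(utils::packageVersion("phzfmech")),
                   R = R.version.string))
  res <- list()
  for (stage in config$stages) {
    res[[stage]] <- switch(stage,
      synth = {
        spec <- phzf_surface_spec("shuttle")
        list(shuttle_spec = spec,
             shuttle_surface = make_mechanism_surface(spec))
      },
      pathfinding = {
        surf <- res$synth$shuttle_surface %||%
          make_mechanism_surface(phzf_surface_spec("shuttle"))
        xi_last <- surf$info$stationary[[3]]$x[1]
        scan <- scan_initial_path(surf, 1, c(0, xi_last), 41)
        cpr <- cpr_refine(surf, scan)
        sp <- classify_stationary(surf, cpr$saddles[[1]]$coordinates)
        list(step1_barrier = barrier(cpr$saddles, 0),
             saddle_order = sp$order,
             saddle_imaginary_cm = sp$frequencies$wavenumber[
               sp$frequencies$imaginary][1])
      },
      titration = {
        dhha <- titratable_system(
          data.frame(label = c("carboxylate", "amino"),
                     pka = c(3.3, 8.6), charge_protonated = c(0, 1)))
        exact <- enumerate_titration(dhha)
        mc <- mc_titrate(dhha, n_steps = 2e4, seed = config$seed + 11)
        list(pka_carboxylate = pka_half(exact, "carboxylate")$pka,
             pka_amino = pka_half(exact, "amino")$pka,
             mc_max_dev = max(abs(mc$prob - exact$prob)),
             mc_seed = config$seed + 11)
      },
      rates = {
        list(intrinsic_kie = kie_from_ddg(0.9, config$kie_temperature),
             semiclassical_limit = semiclassical_kie_limit(
               3000, 12, config$temperature),
             eyring_16_kcal = eyring_rate(16.0, config$temperature),
             e45_pka_from_1.7 = convert_pka_energy(
               1.7, "energy_to_pka", pH = 7.5, T = config$temperature))
      },
      kinetics = {
        tab_H <- .simulate_rate_table(100.34, 517, config$seed + 100,
                                      config$n_conc, config$n_rep)
        tab_D <- .simulate_rate_table(10.60, 311, config$seed + 200,
                                      config$n_conc, config$n_rep,
                                      enzyme_conc = 200)
        fit_H <- fit_michaelis_menten(tab_H)
        fit_D <- fit_michaelis_menten(tab_D)
        kie <- apparent_kie(fit_H, fit_D)
        list(rates_H = tab_H, rates_D = tab_D, fit_H = fit_H,
             fit_D = fit_D, apparent_kie = kie)
      },
      profile = {
        pr <- phzf_profile()
        ob <- overall_barrier(pr)
        list(profile = pr, overall_barrier = ob$barrier,
             limiting_step = ob$limiting_step,
             shift_ranking = rank_mechanisms(phzf_candidates("shift")),
             taut_ranking = rank_mechanisms(
               phzf_candidates("tautomerization")),
             tst = tst_consistency(pr, 3.23, config$temperature))
      })
  }
  report$stages <- res
  report$seeds$kinetics_H <- config$seed + 100
  report$seeds$kinetics_D <- config$seed + 200
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- list()
    if (!is.null(res$profile)) tables$profile <- res$profile$profile
    if (!is.null(res$kinetics)) {
      tables$rates_H <- res$kinetics$rates_H
      tables$rates_D <- res$kinetics$rates_D
    }
    if (length(tables))
      export_tables(tables, format = "tsv", dir = config$out_dir)
    summary_json <- .report_summary(report)
    jsonlite::write_json(summary_json,
                         file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.report_summary <- function(report) {
  s <- report$stages
  out <- list(seeds = report$seeds, versions = report$versions,
              elapsed_s = report$elapsed_s)
  if (!is.null(s$pathfinding))
    out$step1_barrier_kcal <- s$pathfinding$step1_barrier
  if (!is.null(s$titration))
    out$dhha_pkas <- c(s$titration$pka_carboxylate, s$titration$pka_amino)
  if (!is.null(s$rates)) out$rates <- s$rates
  if (!is.null(s$kinetics)) {
    out$fit_H <- list(v_max = s$kinetics$fit_H$v_max,
                      K_M = s$kinetics$fit_H$K_M,
                      k_cat = s$kinetics$fit_H$k_cat)
    out$apparent_kie_vmax <- s$kinetics$apparent_kie$kie_vmax
    out$apparent_kie_vmax_over_km <- s$kinetics$apparent_kie$kie_vmax_over_km
  }
  if (!is.null(s$profile)) {
    out$overall_barrier_kcal <- s$profile$overall_barrier
    out$limiting_step <- s$profile$limiting_step
    out$tst_ratio <- s$profile$tst$ratio
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  str(.report_summary(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Export result tables
#'
#' Writes each element of `results` to `dir`: data frames as TSV/CSV at
#' full precision (17 significant digits), anything else as JSON. Numeric
#' columns named in `reported` conventions (KIE values) are accompanied
#' by a 2-significant-figure `reported` column where applicable.
#'
#' @param results named list of data frames and/or lists.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
export_tables <- function(results, format = "tsv", dir = ".") {
  supported <- c("tsv", "csv", "json")
  if (!format %in% supported)
    stop("unknown format '", format, "'; supported: ",
         paste(supported, collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x) && format != "json") {
      path <- file.path(dir, paste0(nm, ".", format))
      df <- as.data.frame(x)
      for (cl in names(df))
        if (is.numeric(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
      utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                         row.names = FALSE, quote = FALSE)
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back an exported table
#'
#' @param path file written by [export_tables()].
#' @return data frame (TSV/CSV) or list (JSON).
#' @export
import_table <- function(path) {
  ext <- tools::file_ext(path)
  switch(ext,
    tsv = utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE),
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unknown table extension: ", ext))
}

#' @export
as.data.frame.reaction_path <- function(x, ...) {
  df <- as.data.frame(x$frames)
  names(df) <- paste0("q", seq_len(ncol(df)))
  cbind(frame = seq_len(nrow(df)), df, energy = x$energies)
}
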