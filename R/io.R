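#' Read a spectral series from CSV/TSV
#'
#' Expected layout: first column the wavelength (nm), remaining columns
#' one spectrum per temperature with the temperature in degC as column
#' header (a leading "T" or "X" prefix is tolerated).  Temperatures are
#' sorted on read with the matrix permuted accordingly.
#'
#' @param path CSV or TSV file (separator inferred from the extension).
#' @param name series name (defaults to the file name).
#' @return a \code{spectral_series}.
#' @export
read_spectral_series <- function(path, name = basename(path)) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4)
    stop("expected a wavelength column plus >= 3 temperature columns")
  wl <- suppressWarnings(as.numeric(raw[[1]]))
  if (anyNA(wl))
    stop("non-numeric wavelength entries at line(s): ",
         paste(which(is.na(wl)) + 1L, collapse = ", "))
  temps <- suppressWarnings(as.numeric(sub("^[TX]", "", names(raw)[-1])))
  if (anyNA(temps))
    stop("non-numeric temperature headers: ",
         paste(names(raw)[-1][is.na(temps)], collapse = ", "))
  if (anyDuplicated(temps))
    stop("duplicate temperature columns: ",
         paste(temps[duplicated(temps)], collapse = ", "))
  Y <- t(as.matrix(raw[, -1, drop = FALSE]))
  if (!is.numeric(Y)) {
    bad <- which(apply(raw[, -1, drop = FALSE], 1,
                       function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stop("non-numeric absorbance cells at line(s): ",
         paste(bad + 1L, collapse = ", "))
  }
  spectral_series(wl, temps, Y, name = name)
}

#' Write a spectral series as CSV
#'
#' Layout matches \code{\link{read_spectral_series}}: wavelength first
#' column, one temperature (degC) per remaining column.
#'
#' @param series a \code{spectral_series}.
#' @param path output path.
#' @export
write_spectral_series <- function(series, path) {
  tab <- data.frame(wavelength = series$wavelengths,
                    t(series$Y), check.names = FALSE)
  names(tab)[-1] <- format(series$temperatures, trim = TRUE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read chemical-shift profiles from CSV/TSV
#'
#' Expected columns: nucleus, T_C, delta (ppm), optional sigma.
#'
#' @param path file path.
#' @return list of \code{shift_profile}.
#' @export
read_shift_profiles <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("nucleus", "T_C", "delta")
  if (!all(need %in% names(tab)))
    stop("missing columns: ", paste(setdiff(need, names(tab)),
                                    collapse = ", "))
  lapply(split(tab, tab$nucleus), function(g)
    shift_profile(g$nucleus[1], g$T_C, g$delta,
                  if ("sigma" %in% names(tab)) g$sigma else NULL))
}

#' Write chemical-shift profiles as CSV
#' @param profiles list of \code{shift_profile}.
#' @param path output path.
#' @export
write_shift_profiles <- function(profiles, path) {
  tab <- do.call(rbind, lapply(profiles, function(p)
    data.frame(nucleus = p$nucleus, T_C = p$T_C, delta = p$delta,
               sigma = if (is.null(p$sigma)) NA_real_ else p$sigma)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a factor decomposition to a directory
#'
#' Writes S.csv (profiles), V.csv (scores), W.csv (singular values) and
#' summary.json (factor dimension and residuals).
#'
#' @param decomp a \code{factor_decomposition}.
#' @param dir output directory (created if needed).
#' @param M factor dimension to record; estimated when NULL.
#' @export
write_decomposition <- function(decomp, dir, M = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(M)) M <- as.integer(estimate_dimension(decomp))
  utils::write.csv(data.frame(wavelength = decomp$wavelengths,
                              t(decomp$S), check.names = FALSE),
                   file.path(dir, "S.csv"), row.names = FALSE)
  utils::write.csv(data.frame(T_C = decomp$temperatures, decomp$V,
                              check.names = FALSE),
                   file.path(dir, "V.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(decomp$W),
                              W = decomp$W),
                   file.path(dir, "W.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(name = decomp$name, n = decomp$n, p = decomp$p,
         factor_dimension = M,
         residual_rms = decomp$residual_rms),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Serialize a melt fit as JSON
#' @param res a \code{melt_fit_result} or \code{joint_fit_result}.
#' @param path output path.
#' @export
write_fit_json <- function(res, path) {
  out <- if (inherits(res, "melt_fit_result"))
    list(model = res$model, Tm_C = res$Tm_C,
         dH_J_mol = res$params$dH, dS_J_mol_K = res$params$dS,
         se = as.list(res$se), rss = res$rss, n_obs = res$n_obs,
         baselines = res$baselines,
         covariance = res$covariance)
  else
    list(model = "combined",
         hairpin = list(Tm_C = res$Tm_h_C, dH_J_mol = res$hairpin_params$dH,
                        dS_J_mol_K = res$hairpin_params$dS),
         duplex = list(Tm_C_at_nmr_conc = res$Tm_du_C,
                       dH_J_mol = res$duplex_params$dH,
                       dS_J_mol_K = res$duplex_params$dS),
         identifiable = res$identifiable, se = as.list(res$se),
         rss = res$rss, n_obs = res$n_obs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a synthetic UV series and NMR shift profiles, performs the
#' SVD factor analysis, the single-method hairpin fits, the simultaneous
#' combined-model fit with its duplex-fraction curve, and a NOE
#' calibration closure, writing all outputs (CSV/JSON plus a run log
#' with the seeds) to \code{out_dir}.  Rerunning with the same seed
#' reproduces the outputs exactly.
#'
#' @param out_dir output directory.
#' @param seed integer seed for all generators.
#' @param uv_cfg,nmr_cfg \code{synth_config}s for the two datasets;
#'   defaults emulate the measurement conditions (3.08 uM UV series,
#'   1.14 mM NMR series, combined model with a calibrated homoduplex
#'   admixture).
#' @param verbose print stage progress.
#' @return invisibly, a list with the main results.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         uv_cfg = NULL, nmr_cfg = NULL, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  log <- c(sprintf("meltfold pipeline, seed = %d", seed),
           sprintf("R %s", getRversion()), format(Sys.time()))
  hp <- thermo_params_from_tm(60.8, -137000, "hairpin")
  if (is.null(nmr_cfg) || is.null(uv_cfg)) {
    du <- calibrate_duplex_params(-211000, 0.07, 13,
                                  equilibrium_conditions(1.14e-3), hp)
    if (is.null(uv_cfg))
      uv_cfg <- synth_config(seed = seed, model = "combined", hairpin = hp,
                             duplex = du, c = 3.08e-6, noise_sigma = 0.001,
                             T_grid = seq(5, 85, by = 4))
    if (is.null(nmr_cfg))
      nmr_cfg <- synth_config(seed = seed + 1L, model = "combined",
                              hairpin = hp, duplex = du, c = 1.14e-3,
                              noise_sigma = 0.002,
                              T_grid = seq(5, 75, by = 2))
  }
  stage <- "synthesis"
  res <- tryCatch({
    say("stage: ", stage)
    uv <- synth_uv_series(uv_cfg)
    profiles <- synth_shift_profiles(nmr_cfg)
    write_spectral_series(uv, file.path(out_dir, "uv_series.csv"))
    write_shift_profiles(profiles, file.path(out_dir, "shift_profiles.csv"))

    stage <- "svd"
    say("stage: ", stage)
    dec <- decompose(uv)
    M <- as.integer(estimate_dimension(dec, noise_sigma = uv_cfg$noise_sigma))
    write_decomposition(dec, file.path(out_dir, "decomposition"), M)
    log <- c(log, sprintf("factor dimension M = %d", M))

    stage <- "fit-uv"
    say("stage: ", stage)
    cond_uv <- equilibrium_conditions(uv_cfg$c, c_ref = uv_cfg$c_ref)
    fit_uv <- fit_uv_scores(dec, max(M, 2L), "hairpin", cond_uv)
    write_fit_json(fit_uv, file.path(out_dir, "fit_uv.json"))

    stage <- "fit-nmr"
    say("stage: ", stage)
    cond_nmr <- equilibrium_conditions(nmr_cfg$c, c_ref = nmr_cfg$c_ref)
    fit_nmr <- fit_shift_profiles(profiles, "hairpin", cond_nmr)
    write_fit_json(fit_nmr, file.path(out_dir, "fit_nmr.json"))

    stage <- "fit-joint"
    say("stage: ", stage)
    joint <- fit_joint(uv = list(decomp = dec, M = max(M, 2L),
                                 cond = cond_uv),
                       nmr = list(profiles = profiles, cond = cond_nmr))
    write_fit_json(joint, file.path(out_dir, "fit_joint.json"))
    curve <- duplex_fraction_curve(joint, seq(5, 85, by = 1), nmr_cfg$c)
    utils::write.csv(curve, file.path(out_dir, "duplex_fraction.csv"),
                     row.names = FALSE)

    stage <- "noe"
    say("stage: ", stage)
    geom <- data.frame(
      atom_a = c("C-4 H5", "C-5 H5", "A6 H8", "T1 H1'", "A3 H2"),
      atom_b = c("C-4 H6", "C-5 H6", "A6 H1'", "T2 H6", "A-3 H2"),
      d = c(2.9, 2.9, 3.6, 3.1, 3.4))
    peaks <- synth_noesy_peaks(geom, cfg = synth_config(
      seed = seed + 2L, noise_sigma = 0.05))
    dists <- peaks_to_distances(peaks)
    export_restraints(dists, file.path(out_dir, "restraints.tsv"))

    log <- c(log,
             sprintf("UV hairpin fit: Tm = %.2f degC, dH = %.1f kJ/mol",
                     fit_uv$Tm_C, fit_uv$params$dH / 1000),
             sprintf("NMR hairpin fit: Tm = %.2f degC, dH = %.1f kJ/mol",
                     fit_nmr$Tm_C, fit_nmr$params$dH / 1000),
             sprintf("joint fit duplex fraction at 13 degC, %.3g M: %.3f",
                     nmr_cfg$c,
                     duplex_fraction_curve(joint, 13, nmr_cfg$c)$f_du),
             sprintf("seeds used: %d (UV), %d (NMR), %d (NOE)",
                     seed, seed + 1L, seed + 2L))
    list(uv = uv, decomposition = dec, M = M, fit_uv = fit_uv,
         fit_nmr = fit_nmr, joint = joint, distances = dists)
  }, error = function(e) {
    writeLines(c(log, paste("FAILED at stage:", stage),
                 conditionMessage(e)),
               file.path(out_dir, "run_log.txt"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(res)
}
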