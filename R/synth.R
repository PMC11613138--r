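# run expr with a local, restored RNG state so generators are pure
# functions of their seed
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic-data generators
#'
#' Defaults state the measurement conditions the generators emulate: the
#' 16-mer SRE segment melting as a hairpin with Tm = 60.8 degC and
#' dH = -137 kJ/mol (the NMR-determined values; dS follows as dH/Tm),
#' at 1.14 mM strand concentration on a 2 degC grid -- the NMR regime.
#' For UV-style series pass the UV conditions instead (3.08 uM, 5-85
#' degC in 4 degC steps, see examples in the generators).
#'
#' @param seed integer RNG seed.
#' @param model "hairpin", "duplex" or "combined".
#' @param hairpin \code{thermo_params} of the hairpin step.
#' @param duplex \code{thermo_params} of the homoduplex step (required
#'   for "duplex"/"combined").
#' @param c total strand concentration, mol/L.
#' @param c_ref reference concentration, mol/L.
#' @param noise_sigma observation noise sd (absorbance units or ppm).
#' @param T_grid temperatures, degrees Celsius.
#' @export
synth_config <- function(seed = 1L,
                         model = c("hairpin", "duplex", "combined"),
                         hairpin = thermo_params_from_tm(60.8, -137000,
                                                         "hairpin"),
                         duplex = NULL,
                         c = 1.14e-3, c_ref = 1,
                         noise_sigma = 0.002,
                         T_grid = seq(5, 75, by = 2)) {
  model <- match.arg(model)
  if (model %in% c("duplex", "combined") && is.null(duplex))
    stop("model '", model, "' needs duplex thermo_params")
  stopifnot(noise_sigma >= 0, c > 0)
  structure(list(seed = as.integer(seed), model = model, hairpin = hairpin,
                 duplex = duplex, c = c, c_ref = c_ref,
                 noise_sigma = noise_sigma, T_grid = as.numeric(T_grid)),
            class = "synth_config")
}

# species fractions on the config's temperature grid
.synth_fractions <- function(cfg, T_C = cfg$T_grid) {
  T_K <- celsius_to_kelvin(T_C)
  cond <- equilibrium_conditions(cfg$c, c_ref = cfg$c_ref)
  if (cfg$model == "hairpin") {
    K_h <- as.numeric(assoc_constant(cfg$hairpin, T_K))
    fr <- hairpin_fractions(K_h)
  } else if (cfg$model == "duplex") {
    K_du <- as.numeric(assoc_constant(cfg$duplex, T_K))
    fr <- duplex_fractions(K_du, cond)
  } else {
    K_h <- as.numeric(assoc_constant(cfg$hairpin, T_K))
    K_du <- as.numeric(assoc_constant(cfg$duplex, T_K))
    fr <- combined_fractions(K_h, K_du, cond)
  }
  fr$f_folded <- fr$f_h + fr$f_du
  fr
}

#' Synthetic temperature-dependent UV absorption series
#'
#' Folded and unfolded endpoint spectra are smooth analytic bands near
#' 260 nm with configurable hyperchromicity on melting; each state also
#' drifts linearly with temperature (distinct drift shapes), which is
#' what makes the factor dimension of a clean two-state series 4: mean,
#' transition, and the two linear drifts.  Population weighting follows
#' the model in \code{cfg}; i.i.d. Gaussian noise is added and the
#' result is deterministic given the seed.
#'
#' @param cfg a \code{synth_config}; for the UV regime use e.g.
#'   \code{synth_config(model = "hairpin",
#'   hairpin = thermo_params_from_tm(57.4, -137000, "hairpin"),
#'   c = 3.08e-6, noise_sigma = 0.001, T_grid = seq(5, 85, 4))}.
#' @param wavelengths wavelength grid, nm.
#' @param hyperchromicity relative absorbance increase on melting at the
#'   main band.
#' @param drift_folded,drift_unfolded per-state linear drift amplitudes,
#'   absorbance units per degC.
#' @return a \code{spectral_series}.
#' @export
synth_uv_series <- function(cfg, wavelengths = seq(220, 320, by = 1),
                            hyperchromicity = 0.2,
                            drift_folded = 1.2e-3, drift_unfolded = 1.8e-3) {
  stopifnot(inherits(cfg, "synth_config"))
  wl <- as.numeric(wavelengths)
  band <- function(center, width) exp(-(wl - center)^2 / (2 * width^2))
  S_f <- 0.72 * band(258, 16) + 0.45 * band(226, 10)
  S_u <- (1 + hyperchromicity) * 0.72 * band(260, 17) +
    0.45 * band(227, 10)
  D_f <- drift_folded * band(255, 22)
  D_u <- drift_unfolded * band(275, 25)
  T0 <- mean(cfg$T_grid)
  fr <- .synth_fractions(cfg)
  f <- fr$f_folded
  Y <- outer(f, S_f) + outer((1 - f), S_u) +
    outer(f * (cfg$T_grid - T0), D_f) +
    outer((1 - f) * (cfg$T_grid - T0), D_u)
  if (cfg$noise_sigma > 0)
    Y <- Y + .with_seed(cfg$seed,
                        matrix(stats::rnorm(length(Y), 0, cfg$noise_sigma),
                               nrow(Y), ncol(Y)))
  spectral_series(wl, cfg$T_grid, Y,
                  name = sprintf("synthetic UV (%s)", cfg$model),
                  concentration = cfg$c)
}

#' Default aromatic-resonance shift table
#'
#' Linear folded/unfolded state-shift coefficients (ppm and ppm/degC)
#' for the aromatic resonances a global melting fit would use on a
#' 16-mer hairpin: one H6/H8 per nucleotide, one H2 per adenine and one
#' methyl (M7) per thymine, 26 resonances in all.  Intercepts sit in the
#' canonical aromatic ranges per base type and are modulated
#' deterministically along the sequence; transition amplitudes carry
#' both signs, as observed for loop versus stem protons.
#'
#' @param seq an \code{oligo_sequence}; default the 16-mer SRE segment.
#' @return data frame (label, delta_f0, delta_f1, delta_u0, delta_u1).
#' @export
default_resonance_table <- function(seq = build_sre_segment(16)) {
  base_h <- c(A = 8.20, G = 7.80, T = 7.25, C = 7.45)  # H8/H8/H6/H6
  atom_h <- c(A = "H8", G = "H8", T = "H6", C = "H6")
  rows <- list()
  add <- function(label, f0, f1, u0, u1)
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, delta_f0 = f0, delta_f1 = f1,
      delta_u0 = u0, delta_u1 = u1)
  for (i in seq_len(seq$N)) {
    b <- seq$bases[i]
    pos <- seq$positions[i]
    mod <- 0.12 * sin(1.7 * i)           # deterministic sequence variation
    amp <- 0.18 * cos(0.9 * i + 0.4)     # signed transition amplitude
    f0 <- base_h[[b]] + mod
    add(sprintf("%s%d %s", b, pos, atom_h[[b]]),
        f0, -3e-4 * sin(i), f0 + amp, -6e-4)
    if (b == "A") {
      f0a <- 7.55 + mod
      add(sprintf("A%d H2", pos), f0a, 2e-4 * cos(i), f0a - amp, -4e-4)
    }
    if (b == "T") {
      f0m <- 1.40 + 0.5 * mod
      add(sprintf("T%d M7", pos), f0m, 4e-4, f0m + 0.8 * amp, -2e-4)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic chemical-shift melting profiles
#'
#' Fast-exchange observed shifts: delta(T) = f(T) (delta_f0 +
#' delta_f1 T) + (1 - f(T)) (delta_u0 + delta_u1 T) with f from the
#' model in \code{cfg}, plus Gaussian noise; deterministic given the
#' seed.
#'
#' @param cfg a \code{synth_config} (noise_sigma in ppm).
#' @param resonance_table data frame as from
#'   \code{\link{default_resonance_table}}.
#' @return list of \code{shift_profile}.
#' @export
synth_shift_profiles <- function(cfg,
                                 resonance_table = default_resonance_table()) {
  stopifnot(inherits(cfg, "synth_config"))
  f <- .synth_fractions(cfg)$f_folded
  Tt <- cfg$T_grid
  noise <- if (cfg$noise_sigma > 0)
    .with_seed(cfg$seed,
               matrix(stats::rnorm(length(Tt) * nrow(resonance_table),
                                   0, cfg$noise_sigma),
                      length(Tt), nrow(resonance_table)))
  else matrix(0, length(Tt), nrow(resonance_table))
  lapply(seq_len(nrow(resonance_table)), function(i) {
    r <- resonance_table[i, ]
    delta <- f * (r$delta_f0 + r$delta_f1 * Tt) +
      (1 - f) * (r$delta_u0 + r$delta_u1 * Tt) + noise[, i]
    sigma <- if (cfg$noise_sigma > 0) rep(cfg$noise_sigma, length(Tt))
             else NULL
    shift_profile(r$label, Tt, delta, sigma)
  })
}

#' Synthetic NOESY cross-peak volumes from a known geometry
#'
#' Volumes follow the sixth-power rule I = scale * d^-6 (1 + eps) with
#' eps ~ N(0, noise); methyl-group peaks get three times the volume
#' (three equivalent protons), matching the pseudo-atom convention used
#' on analysis.  Include at least one intranucleotide cytosine H5-H6
#' pair at 2.9 A so the analysis can self-calibrate.
#'
#' @param geometry data frame (atom_a, atom_b, d) with distances in
#'   Angstrom.
#' @param scale overall intensity scale.
#' @param cfg a \code{synth_config}; \code{noise_sigma} is the relative
#'   volume noise.
#' @return list of \code{cross_peak}.
#' @export
synth_noesy_peaks <- function(geometry, scale = 1e6, cfg = synth_config()) {
  stopifnot(all(geometry$d > 0))
  eps <- if (cfg$noise_sigma > 0)
    .with_seed(cfg$seed, stats::rnorm(nrow(geometry), 0, cfg$noise_sigma))
  else rep(0, nrow(geometry))
  lapply(seq_len(nrow(geometry)), function(i) {
    g <- geometry[i, ]
    n_methyl <- sum(grepl("M", c(g$atom_a, g$atom_b), fixed = TRUE))
    vol <- scale * 3^n_methyl * g$d^-6 * (1 + eps[i])
    cross_peak(g$atom_a, g$atom_b, vol)
  })
}

# one block of a reference fluorescence pattern: smooth emission /
# excitation band on the stated instrument grids
.fluor_blocks_template <- function() {
  list(fam_em = seq(500, 680, by = 2),
       fam_exc = seq(404, 514, by = 2),
       cy3_em = seq(550, 680, by = 2),
       cy3_exc = seq(404, 552, by = 2))
}

.fluor_pattern_from_amps <- function(sample, amps, shift = 0) {
  grids <- .fluor_blocks_template()
  shape <- function(wl, center, width) exp(-(wl - center)^2 / (2 * width^2))
  blocks <- list(
    fam_em = data.frame(wavelength = grids$fam_em,
                        intensity = amps["fam"] *
                          shape(grids$fam_em, 521 + shift, 18)),
    fam_exc = data.frame(wavelength = grids$fam_exc,
                         intensity = amps["fam"] *
                           shape(grids$fam_exc, 492 + shift, 16)),
    cy3_em = data.frame(wavelength = grids$cy3_em,
                        intensity = amps["cy3"] *
                          shape(grids$cy3_em, 563 + shift, 15) +
                          amps["fret"] * shape(grids$cy3_em, 563 + shift, 15)),
    cy3_exc = data.frame(wavelength = grids$cy3_exc,
                         intensity = amps["cy3"] *
                           shape(grids$cy3_exc, 549 + shift, 17) +
                           amps["fret"] * shape(grids$cy3_exc, 492 + shift, 16)))
  fluorescence_pattern(sample, blocks)
}

#' Synthetic reference fluorescence patterns
#'
#' Three reference patterns for the doubly labeled strand: "hairpin"
#' (fluorophores close, strongly quenched, small FRET leak), "free"
#' (open coil, unquenched but red-shifted a few nm by solvent exposure),
#' "duplex" (heteroduplex with the unlabeled strand, fluorophores apart,
#' unquenched).  Photophysics is not modeled; quench/unquench lives
#' entirely in these vectors.
#'
#' @return named list of \code{fluorescence_pattern}.
#' @export
synth_reference_patterns <- function() {
  list(
    hairpin = .fluor_pattern_from_amps(
      "hairpin", c(fam = 0.22, cy3 = 0.30, fret = 0.10)),
    free = .fluor_pattern_from_amps(
      "free", c(fam = 0.65, cy3 = 0.70, fret = 0.03), shift = 4),
    duplex = .fluor_pattern_from_amps(
      "duplex", c(fam = 1.00, cy3 = 0.95, fret = 0.00)))
}

#' Synthetic labeled/unlabeled titration series
#'
#' Emulates the homoduplex titration: a trace of doubly labeled strand
#' (0.1 uM) mixed with an excess of unlabeled strand at ratios up to
#' 1:3000.  Each point's pattern is the species-fraction-weighted sum of
#' the reference patterns plus Gaussian noise; deterministic given the
#' seed.
#'
#' @param cfg a \code{synth_config}; \code{noise_sigma} is the absolute
#'   intensity noise on the unit-scaled patterns.
#' @param K_du duplex association constant, M^-1 scale (dimensionless at
#'   c_ref = 1 M).
#' @param K_h dimensionless hairpin association constant at the working
#'   temperature (21 degC in the experiment).
#' @param references named list with elements "hairpin", "free",
#'   "duplex" as from \code{\link{synth_reference_patterns}}.
#' @param ratios unlabeled:labeled concentration ratios.
#' @param c_labeled labeled strand concentration, mol/L.
#' @return list of \code{titration_point}.
#' @export
synth_titration <- function(cfg, K_du, K_h,
                            references = synth_reference_patterns(),
                            ratios = c(1, 3, 10, 30, 100, 300, 1000, 3000),
                            c_labeled = 1e-7) {
  stopifnot(all(ratios > 0))
  n_chan <- length(references$hairpin$intensity)
  noise <- if (cfg$noise_sigma > 0)
    .with_seed(cfg$seed,
               matrix(stats::rnorm(n_chan * length(ratios),
                                   0, cfg$noise_sigma),
                      n_chan, length(ratios)))
  else matrix(0, n_chan, length(ratios))
  lapply(seq_along(ratios), function(i) {
    cu <- ratios[i] * c_labeled
    fr <- labeled_duplex_fraction(K_du, K_h, c_labeled, cu, cfg$c_ref)
    intensity <- fr$f_h * references$hairpin$intensity +
      fr$f_free * references$free$intensity +
      fr$f_du * references$duplex$intensity +
      noise[, i]
    intensity <- pmax(intensity, 0)
    pat <- references$hairpin
    pat$sample <- sprintf("titration 1:%g", ratios[i])
    pat$intensity <- intensity
    ofs <- 0L
    for (nm in names(pat$blocks)) {
      nrows <- nrow(pat$blocks[[nm]])
      pat$blocks[[nm]]$intensity <- intensity[ofs + seq_len(nrows)]
      ofs <- ofs + nrows
    }
    titration_point(c_labeled, cu, pat)
  })
}

#' Duplex entropy matching a target duplex strand fraction
#'
#' Solves for the duplex association entropy that, combined with a given
#' duplex enthalpy and hairpin parameters, makes the combined model give
#' a stated duplex strand fraction at one temperature and concentration.
#' Used to state generator truths like "7 percent of strands in
#' homoduplexes at 13 degC and 1.14 mM".
#'
#' @param dH_du duplex association enthalpy, J/mol.
#' @param f_du_target target duplex strand fraction (0..1).
#' @param T_C temperature, degC.
#' @param cond an \code{equilibrium_conditions} (total strand
#'   concentration).
#' @param hairpin hairpin \code{thermo_params}.
#' @return duplex \code{thermo_params}.
#' @export
calibrate_duplex_params <- function(dH_du, f_du_target, T_C, cond,
                                    hairpin) {
  stopifnot(f_du_target > 0, f_du_target < 1)
  T_K <- celsius_to_kelvin(T_C)
  K_h <- as.numeric(assoc_constant(hairpin, T_K))
  c_un <- (1 - f_du_target) * cond$c / (1 + K_h)
  Kp <- f_du_target * cond$c / (2 * c_un^2)
  K_du <- Kp * cond$c_ref
  dS <- dH_du / T_K + R_GAS * log(K_du)
  thermo_params(dH_du, dS, label = "calibrated homoduplex")
}
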