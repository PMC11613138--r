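cond_uv <- equilibrium_conditions(3.08e-6)
cond_nmr <- equilibrium_conditions(1.14e-3)

test_that("UV score fits recover the generator thermodynamics", {
  d <- decompose(synth_uv_series(uv_cfg16(seed = 4)))
  fit <- fit_uv_scores(d, 4, "hairpin", cond_uv)
  expect_lt(abs(fit$Tm_C - 57.4), 0.5)
  expect_lt(abs(fit$params$dH + 137000) / 137000, 0.05)
  expect_error(fit_uv_scores(d, 1, "hairpin", cond_uv), "between 2")
})

test_that("noiseless UV scores are fitted to optimizer precision", {
  d <- decompose(synth_uv_series(uv_cfg16(seed = 1, noise_sigma = 0)))
  fit <- fit_uv_scores(d, 4, "hairpin", cond_uv)
  expect_lt(fit$rss, 1e-18)
  expect_lt(abs(fit$Tm_C - 57.4), 1e-3)
  expect_lt(abs(fit$params$dH + 137000), 10)
})

test_that("hairpin and duplex models fit one concentration equally well", {
  # the single-series degeneracy: both molecularities reproduce the same
  # sigmoid to visually unresolvable residuals (the bimolecular fit
  # trades a larger |dH| for the broader mass-action transition)
  d <- decompose(synth_uv_series(uv_cfg16(seed = 6)))
  f_h <- fit_uv_scores(d, 4, "hairpin", cond_uv)
  f_d <- fit_uv_scores(d, 4, "duplex", cond_uv)
  for (f in list(f_h, f_d)) {
    s2 <- f$fitted[f$fitted$channel == "score2", ]
    expect_lt(max(abs(s2$fitted - s2$y)), 0.01 * diff(range(s2$y)))
  }
  # the bimolecular reading of a unimolecular transition inflates |dH|
  expect_gt(abs(f_d$params$dH), abs(f_h$params$dH) * 1.3)
  expect_lt(f_d$Tm_C, f_h$Tm_C)
})

test_that("global shift fits recover Tm and dH within tolerance", {
  profiles <- synth_shift_profiles(nmr_cfg16(seed = 8))
  fit <- fit_shift_profiles(profiles, "hairpin", cond_nmr)
  expect_lt(abs(fit$Tm_C - 60.8), 0.5)
  expect_lt(abs(fit$params$dH + 137000) / 137000, 0.03)
  expect_error(fit_shift_profiles(list(), "hairpin", cond_nmr),
               "no profiles")
  expect_error(shift_profile("X", 1:4, 1:4), "length >= 5")
})

test_that("single noiseless profile is recovered exactly", {
  prof <- synth_shift_profiles(nmr_cfg16(seed = 1, noise_sigma = 0),
                               small_resonances(1))
  fit <- fit_shift_profiles(prof, "hairpin", cond_nmr)
  expect_lt(abs(fit$Tm_C - 60.8), 1e-4)
  expect_lt(abs(fit$params$dH + 137000), 10)
})

test_that("opposite-sign shift amplitudes give one global Tm", {
  tab <- default_resonance_table()
  amps <- tab$delta_u0 - tab$delta_f0
  expect_true(any(amps > 0) && any(amps < 0))  # mixed directions
  # sign invariance, not precision, is the point here: the global Tm
  # must land on the single transition despite curves crossing
  fit <- fit_shift_profiles(
    synth_shift_profiles(nmr_cfg16(seed = 9), tab), "hairpin", cond_nmr)
  expect_lt(abs(fit$Tm_C - 60.8), 1.5)
})

test_that("parameter recovery holds across seeded replicates", {
  reps <- lapply(1:20, function(s)
    fit_shift_profiles(synth_shift_profiles(nmr_cfg16(seed = 100 + s)),
                       "hairpin", cond_nmr))
  dTm <- vapply(reps, function(f) abs(f$Tm_C - 60.8), numeric(1))
  ddH <- vapply(reps, function(f)
    abs(f$params$dH + 137000) / 137000, numeric(1))
  expect_lt(median(dTm), 0.5)
  expect_lt(median(ddH), 0.05)
})

test_that("per-resonance melting points cluster within one degree", {
  # high-precision shift readings: all resonances share one transition
  prof <- synth_shift_profiles(nmr_cfg16(seed = 10, noise_sigma = 1e-4),
                               small_resonances(12))
  tms <- per_resonance_tm(prof, "hairpin", cond_nmr)
  expect_true(all(tms$flag == "ok"))
  expect_lt(diff(range(tms$Tm_C)), 1)

  # zero transition amplitude is flagged, without aborting the batch
  flat <- shift_profile("flat H6", seq(5, 75, 2),
                        7.4 + 1e-4 * seq(5, 75, 2) +
                          rnorm(36, 0, 2e-4))
  mixed <- per_resonance_tm(c(prof[1:2], list(flat)), "hairpin", cond_nmr)
  expect_equal(mixed$flag, c("ok", "ok", "no transition"))
})

test_that("a two-population mixture yields a bimodal Tm list", {
  lo <- nmr_cfg16(seed = 11, noise_sigma = 2e-4)
  hi <- nmr_cfg16(seed = 12, noise_sigma = 2e-4)
  hi$hairpin <- thermo_params_from_tm(45, -137000, "hairpin")
  prof <- c(synth_shift_profiles(lo, small_resonances(4)),
            synth_shift_profiles(hi, small_resonances(4)))
  tms <- per_resonance_tm(prof, "hairpin", cond_nmr)$Tm_C
  expect_equal(sum(abs(tms - 60.8) < 1.5), 4)
  expect_equal(sum(abs(tms - 45.0) < 1.5), 4)
})

test_that("duplex-model fits see the concentration shift, hairpin fits do not", {
  # duplex truth at two concentrations, same (dH, dS)
  cond1 <- equilibrium_conditions(1.06e-3)
  cond2 <- equilibrium_conditions(1.06e-5)
  p_du <- thermo_params_from_tm(45.7, -252000, "duplex", cond1)
  mk <- function(cond, seed) {
    cfg <- synth_config(seed = seed, model = "duplex", duplex = p_du,
                        c = cond$c, noise_sigma = 5e-4,
                        T_grid = seq(5, 75, 2))
    synth_shift_profiles(cfg)
  }
  f1 <- fit_shift_profiles(mk(cond1, 13), "duplex", cond1)
  f2 <- fit_shift_profiles(mk(cond2, 14), "duplex", cond2)
  # same underlying thermodynamics at both concentrations
  expect_lt(abs(f1$params$dH - f2$params$dH) / abs(f1$params$dH), 0.05)
  # observed midpoint shifts down ~ R ln(10)/|dS'| * 2 decades
  expect_lt(f2$Tm_C, f1$Tm_C - 5)
  # hairpin fits of hairpin truth at two concentrations agree instead
  # (median over seed pairs, since each Tm carries ~0.5 degC noise)
  dt <- vapply(c(15, 25, 35), function(s) {
    h1 <- fit_shift_profiles(
      synth_shift_profiles(nmr_cfg16(seed = s, noise_sigma = 5e-4)),
      "hairpin", cond_nmr)
    cfg_lo <- nmr_cfg16(seed = s + 1, noise_sigma = 5e-4)
    cfg_lo$c <- 1.14e-5
    h2 <- fit_shift_profiles(
      synth_shift_profiles(cfg_lo), "hairpin",
      equilibrium_conditions(1.14e-5))
    abs(h1$Tm_C - h2$Tm_C)
  }, numeric(1))
  expect_lt(median(dt), 0.5)
})

test_that("duplex melting of the reference octamer is recovered", {
  cond8 <- equilibrium_conditions(1.06e-3)
  cfg <- synth_config(seed = 17, model = "duplex",
                      duplex = thermo_params_from_tm(45.7, -252000,
                                                     "duplex", cond8),
                      c = 1.06e-3, noise_sigma = 0.002,
                      T_grid = seq(5, 75, 2))
  fit <- fit_shift_profiles(synth_shift_profiles(cfg), "duplex", cond8)
  expect_lt(abs(fit$Tm_C - 45.7), 0.5)
  expect_lt(abs(fit$params$dH + 252000) / 252000, 0.05)
})

joint_fixture <- function(seed, f_du_13 = 0.07) {
  hp <- thermo_params_from_tm(60.8, -137000, "hairpin")
  du <- calibrate_duplex_params(-211000, f_du_13, 13,
                                equilibrium_conditions(1.14e-3), hp)
  uv_cfg <- synth_config(seed = seed, model = "combined", hairpin = hp,
                         duplex = du, c = 3.08e-6, noise_sigma = 0.001,
                         T_grid = seq(5, 85, 4))
  nmr_cfg <- synth_config(seed = seed + 1000L, model = "combined",
                          hairpin = hp, duplex = du, c = 1.14e-3,
                          noise_sigma = 5e-4, T_grid = seq(5, 75, 2))
  list(uv = list(decomp = decompose(synth_uv_series(uv_cfg)), M = 4L,
                 cond = cond_uv, noise_sigma = 0.001),
       nmr = list(profiles = synth_shift_profiles(nmr_cfg),
                  cond = cond_nmr))
}

test_that("the simultaneous fit recovers the duplex admixture", {
  fx <- joint_fixture(seed = 31)
  jf <- fit_joint(uv = fx$uv, nmr = fx$nmr)
  expect_true(jf$identifiable)
  expect_lt(abs(jf$Tm_h_C - 60.8), 1)
  f13 <- duplex_fraction_curve(jf, 13, 1.14e-3)$f_du
  expect_lt(abs(f13 - 0.07), 0.03)
})

test_that("a duplex-free generator yields a negligible fitted duplex", {
  # noiseless null case: the combined model must not invent duplexes
  hp <- thermo_params_from_tm(60.8, -137000, "hairpin")
  uv_cfg <- synth_config(seed = 41, model = "hairpin", hairpin = hp,
                         c = 3.08e-6, noise_sigma = 0,
                         T_grid = seq(5, 85, 4))
  nmr_cfg <- synth_config(seed = 42, model = "hairpin", hairpin = hp,
                          c = 1.14e-3, noise_sigma = 0,
                          T_grid = seq(5, 75, 2))
  jf <- fit_joint(uv = list(decomp = decompose(synth_uv_series(uv_cfg)),
                            M = 2L, cond = cond_uv, noise_sigma = 1e-6),
                  nmr = list(profiles = synth_shift_profiles(nmr_cfg),
                             cond = cond_nmr))
  curve <- duplex_fraction_curve(jf, seq(5, 85, 5), 1.14e-3)
  expect_lt(max(curve$f_du), 0.01)
})

test_that("single-method input is refused as not separable", {
  fx <- joint_fixture(seed = 51)
  expect_error(fit_joint(uv = fx$uv), "not separable")
  expect_error(fit_joint(nmr = fx$nmr), "not separable")
  # near-equal concentrations only warn
  nmr_close <- fx$nmr
  nmr_close$cond <- equilibrium_conditions(5e-6)
  expect_warning(try(fit_joint(uv = fx$uv, nmr = nmr_close),
                     silent = TRUE), "10x")
})

test_that("duplex fraction curves respect temperature and concentration limits", {
  fx <- joint_fixture(seed = 61)
  jf <- fit_joint(uv = fx$uv, nmr = fx$nmr)
  # far above both transitions nothing is folded
  expect_lt(duplex_fraction_curve(jf, 95, 1.14e-3)$f_du, 0.02)
  # bimolecularity: f_du vanishes with dilution and grows with c
  expect_lt(duplex_fraction_curve(jf, 13, 1e-12)$f_du, 1e-6)
  expect_gt(duplex_fraction_curve(jf, 13, 1.14e-3)$f_du,
            duplex_fraction_curve(jf, 13, 3.08e-6)$f_du)
})
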