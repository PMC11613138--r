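#' A temperature profile of a chemical shift
#'
#' In fast exchange the observed shift is the population-weighted mean of
#' the folded and unfolded state shifts, each assumed linear in
#' temperature.
#'
#' @param nucleus resonance label, e.g. "A6 H8".
#' @param T_C temperatures, degrees Celsius (sorted, length >= 5).
#' @param delta chemical shifts, ppm.
#' @param sigma optional per-point uncertainty, ppm.
#' @export
shift_profile <- function(nucleus, T_C, delta, sigma = NULL) {
  if (length(T_C) != length(delta) || length(T_C) < 5)
    stop("need matched T/delta arrays of length >= 5")
  o <- order(T_C)
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(T_C), all(sigma > 0))
    sigma <- sigma[o]
  }
  structure(list(nucleus = nucleus, T_C = as.numeric(T_C[o]),
                 delta = as.numeric(delta[o]), sigma = sigma),
            class = "shift_profile")
}

# ---------------------------------------------------------------------------
# internal variable-projection fitting engine
#
# A "channel" is one observable trace: list(T_C, y, w (per-point weights,
# channel scale included), label, cond).  pops_fun(theta, ch) returns an
# n x k matrix of population fractions; each population carries a linear
# baseline a + b*T_C solved exactly by weighted least squares, so the
# outer optimization runs over the nonlinear parameters theta only.
# ---------------------------------------------------------------------------

.channel <- function(T_C, y, w = NULL, label = "", cond = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  if (length(w) == 1L) w <- rep(w, length(y))
  list(T_C = as.numeric(T_C), y = as.numeric(y), w = as.numeric(w),
       label = label, cond = cond)
}

.channel_design <- function(P, T_C) {
  X <- matrix(0, nrow(P), 2L * ncol(P))
  for (k in seq_len(ncol(P))) {
    X[, 2L * k - 1L] <- P[, k]
    X[, 2L * k] <- P[, k] * T_C
  }
  X
}

# group channels that share a temperature grid, conditions and per-point
# weight profile (up to a channel-level scale): the linear baseline solve
# is then one multi-RHS QR per group instead of one solve per channel
.make_groups <- function(channels) {
  key <- vapply(channels, function(ch) {
    w1 <- ch$w / ch$w[1]
    paste(c(format(ch$T_C, digits = 12), format(w1, digits = 12),
            format(unlist(ch$cond), digits = 12)), collapse = ",")
  }, character(1))
  lapply(split(seq_along(channels), factor(key, unique(key))),
         function(idx) {
    first <- channels[[idx[1]]]
    list(T_C = first$T_C, cond = first$cond,
         Y = vapply(channels[idx], `[[`, numeric(length(first$y)), "y"),
         w_point = first$w / first$w[1],
         w_chan = vapply(channels[idx], function(ch) ch$w[1], numeric(1)),
         labels = vapply(channels[idx], `[[`, character(1), "label"),
         idx = idx)
  })
}

.group_solve <- function(theta, grp, pops_fun) {
  P <- pops_fun(theta, grp)
  if (anyNA(P) || any(!is.finite(P))) return(NULL)
  X <- .channel_design(P, grp$T_C)
  sw <- sqrt(grp$w_point)
  qrX <- qr(X * sw)
  beta <- qr.coef(qrX, grp$Y * sw)
  beta[is.na(beta)] <- 0
  fitted <- X %*% beta
  list(beta = beta, fitted = fitted, resid = grp$Y - fitted)
}

.varpro_rss <- function(theta, groups, pops_fun) {
  total <- 0
  for (grp in groups) {
    sol <- .group_solve(theta, grp, pops_fun)
    if (is.null(sol)) return(1e12)
    total <- total +
      sum(grp$w_chan * colSums(grp$w_point * sol$resid^2))
  }
  total
}

.varpro_solve <- function(theta, groups, pops_fun) {
  out <- list()
  for (grp in groups) {
    sol <- .group_solve(theta, grp, pops_fun)
    for (k in seq_along(grp$idx))
      out[[grp$idx[k]]] <- list(coef = sol$beta[, k],
                                fitted = sol$fitted[, k],
                                residuals = sol$resid[, k])
  }
  out
}

# crude transition-temperature guess: temperature of the steepest change
.guess_tm <- function(channels) {
  est <- vapply(channels, function(ch) {
    if (length(ch$y) < 4) return(c(NA_real_, 0))
    dy <- abs(diff(ch$y) / diff(ch$T_C))
    mid <- (ch$T_C[-1] + ch$T_C[-length(ch$T_C)]) / 2
    c(mid[which.max(dy)], diff(range(ch$y)))
  }, numeric(2))
  w <- est[2, ]
  if (all(w == 0)) return(mean(channels[[1]]$T_C))
  sum(est[1, ] * w, na.rm = TRUE) / sum(w)
}

.fit_nonlinear <- function(groups, pops_fun, starts, lower, upper) {
  obj <- function(theta) {
    if (any(theta < lower) || any(theta > upper))
      return(1e10 * (1 + sum(pmax(lower - theta, 0) + pmax(theta - upper, 0))))
    .varpro_rss(theta, groups, pops_fun)
  }
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ref <- tryCatch(
    stats::optim(best$par, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) best)
  if (ref$value <= best$value) best <- ref
  best
}

.nl_covariance <- function(theta, groups, pops_fun, sigma2) {
  H <- tryCatch(
    stats::optimHess(theta, function(th) .varpro_rss(th, groups, pops_fun)),
    error = function(e) NULL)
  if (is.null(H)) return(NULL)
  cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
  if (!is.null(cov) && any(diag(cov) < 0)) cov <- NULL
  cov
}

# population fractions for the single-transition models
.two_state_pops <- function(model) {
  function(theta, ch) {
    Tm_C <- theta[1]
    dH <- theta[2] * 1000            # optimizer works in kJ/mol
    p <- thermo_params_from_tm(Tm_C, dH, model, ch$cond)
    K <- as.numeric(assoc_constant(p, celsius_to_kelvin(ch$T_C)))
    f <- if (model == "hairpin") K / (1 + K)
         else duplex_fractions(K, ch$cond)$f_du
    cbind(folded = f, unfolded = 1 - f)
  }
}

.two_state_starts <- function(channels) {
  tm0 <- .guess_tm(channels)
  list(c(tm0, -150), c(tm0 - 8, -150), c(tm0 + 8, -150),
       c(tm0, -80), c(tm0, -280))
}

.melt_fit <- function(channels, model, cond) {
  for (i in seq_along(channels))
    if (is.null(channels[[i]]$cond)) channels[[i]]$cond <- cond
  pops <- .two_state_pops(model)
  groups <- .make_groups(channels)
  best <- .fit_nonlinear(groups, pops, .two_state_starts(channels),
                         lower = c(-40, -2000), upper = c(150, -1))
  theta <- best$par
  sol <- .varpro_solve(theta, groups, pops)
  n_obs <- sum(vapply(channels, function(ch) length(ch$y), 0L))
  n_par <- 2L + 4L * length(channels)
  dof <- max(n_obs - n_par, 1L)
  sigma2 <- best$value / dof
  cov_nl <- .nl_covariance(theta, groups, pops, sigma2)
  Tm_C <- theta[1]
  dH <- theta[2] * 1000
  params <- thermo_params_from_tm(Tm_C, dH, model, cond)
  Tm_K <- celsius_to_kelvin(Tm_C)
  se <- c(Tm_C = NA_real_, dH = NA_real_, dS = NA_real_)
  if (!is.null(cov_nl)) {
    se["Tm_C"] <- sqrt(cov_nl[1, 1])
    se["dH"] <- sqrt(cov_nl[2, 2]) * 1000
    # delta method for dS = dH/Tm_K (- R log(c/c_ref) constant)
    g <- c(-dH / Tm_K^2, 1000 / Tm_K)
    se["dS"] <- sqrt(drop(t(g) %*% cov_nl %*% g))
  }
  baselines <- do.call(rbind, lapply(seq_along(channels), function(i) {
    co <- sol[[i]]$coef
    data.frame(channel = channels[[i]]$label,
               folded_a = co[1], folded_b = co[2],
               unfolded_a = co[3], unfolded_b = co[4])
  }))
  fitted <- lapply(seq_along(channels), function(i)
    data.frame(channel = channels[[i]]$label, T_C = channels[[i]]$T_C,
               y = channels[[i]]$y, fitted = sol[[i]]$fitted))
  structure(list(params = params, Tm_C = Tm_C, Tm_K = Tm_K,
                 model = model, cond = cond, se = se,
                 covariance = cov_nl, rss = best$value, sigma2 = sigma2,
                 n_obs = n_obs, baselines = baselines,
                 fitted = do.call(rbind, fitted),
                 convergence = best$convergence),
            class = "melt_fit_result")
}

#' @export
print.melt_fit_result <- function(x, ...) {
  cat(sprintf("<melt_fit_result> %s model\n", x$model))
  cat(sprintf("  Tm = %.2f +/- %.2f degC   dH = %.1f +/- %.1f kJ/mol   dS = %.1f +/- %.1f J/mol/K\n",
              x$Tm_C, x$se["Tm_C"], x$params$dH / 1000, x$se["dH"] / 1000,
              x$params$dS, x$se["dS"]))
  cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n_obs))
  invisible(x)
}

#' Fit a two-state melting model to SVD score columns
#'
#' All M leading score columns are fitted jointly: each column j follows
#' score_j(T) = f(T) (a_j + b_j T) + (1 - f(T)) (c_j + d_j T) with a single
#' shared (Tm, dH) driving the folded fraction f(T) through the chosen
#' model.  Residuals of column j are weighted by (W_j/W_1)^2 so that the
#' fit works in absorbance units.
#'
#' @param decomp a \code{factor_decomposition}.
#' @param M number of score columns to fit (>= 2), e.g. from
#'   \code{\link{estimate_dimension}}.
#' @param model "hairpin" (unimolecular) or "duplex" (bimolecular).
#' @param cond an \code{equilibrium_conditions} with the total strand
#'   concentration of the series.
#' @return a \code{melt_fit_result}.
#' @export
fit_uv_scores <- function(decomp, M, model = c("hairpin", "duplex"), cond) {
  model <- match.arg(model)
  stopifnot(inherits(decomp, "factor_decomposition"))
  if (M < 2 || M > length(decomp$W))
    stop("M must be between 2 and the rank of the decomposition")
  channels <- lapply(seq_len(M), function(j)
    .channel(decomp$temperatures, decomp$V[, j],
             w = rep((decomp$W[j] / decomp$W[1])^2, decomp$n),
             label = sprintf("score%d", j), cond = cond))
  .melt_fit(channels, model, cond)
}

#' Fit a two-state melting model to chemical-shift profiles
#'
#' Each profile keeps its own folded/unfolded linear state shifts while a
#' single (Tm, dH) is shared across all profiles (\code{shared = TRUE}),
#' reproducing the global joint fit of all aromatic shifts.  Points with
#' per-point sigmas are weighted by 1/sigma^2.
#'
#' @param profiles list of \code{shift_profile}.
#' @param model "hairpin" or "duplex".
#' @param cond an \code{equilibrium_conditions}.
#' @param shared must be TRUE here; use \code{\link{per_resonance_tm}} for
#'   independent per-resonance fits.
#' @return a \code{melt_fit_result}.
#' @export
fit_shift_profiles <- function(profiles, model = c("hairpin", "duplex"),
                               cond, shared = TRUE) {
  model <- match.arg(model)
  if (inherits(profiles, "shift_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no profiles supplied")
  if (!shared) stop("use per_resonance_tm() for independent fits")
  channels <- lapply(profiles, function(p) {
    if (length(p$T_C) < 5) stop("fewer than 5 points in profile ", p$nucleus)
    w <- if (is.null(p$sigma)) NULL else 1 / p$sigma^2
    .channel(p$T_C, p$delta, w, label = p$nucleus, cond = cond)
  })
  .melt_fit(channels, model, cond)
}

#' Per-resonance melting temperatures
#'
#' Fits every profile separately and reports one Tm per resonance with its
#' standard error.  A profile whose fitted transition amplitude does not
#' exceed five times the residual scatter is flagged "no transition"; fit
#' failures are reported per profile without aborting the batch.
#'
#' @param profiles list of \code{shift_profile}.
#' @param model "hairpin" or "duplex".
#' @param cond an \code{equilibrium_conditions}.
#' @return data frame (nucleus, Tm_C, se, flag).
#' @export
per_resonance_tm <- function(profiles, model = c("hairpin", "duplex"), cond) {
  model <- match.arg(model)
  if (inherits(profiles, "shift_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    res <- tryCatch(fit_shift_profiles(list(p), model, cond),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(nucleus = p$nucleus, Tm_C = NA_real_,
                        se = NA_real_, flag = conditionMessage(res)))
    b <- res$baselines[1, ]
    amp <- abs((b$folded_a + b$folded_b * res$Tm_C) -
               (b$unfolded_a + b$unfolded_b * res$Tm_C))
    noise <- stats::sd(res$fitted$y - res$fitted$fitted)
    in_range <- res$Tm_C >= min(p$T_C) && res$Tm_C <= max(p$T_C)
    flag <- if (!in_range || !is.finite(amp) || amp < 5 * noise)
      "no transition" else "ok"
    data.frame(nucleus = p$nucleus,
               Tm_C = if (flag == "ok") res$Tm_C else NA_real_,
               se = if (flag == "ok") unname(res$se["Tm_C"]) else NA_real_,
               flag = flag)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# simultaneous UV + NMR combined-model fit
# ---------------------------------------------------------------------------

.joint_pops <- function(share_folded, cond_du_ref) {
  function(theta, ch) {
    # theta: (Tm_h_C, dH_h kJ, Tm_du_C at the reference concentration,
    #         dH_du kJ); dS_du is derived, for conditioning
    ph <- thermo_params_from_tm(theta[1], theta[2] * 1000, "hairpin")
    pdu <- thermo_params_from_tm(theta[3], theta[4] * 1000, "duplex",
                                 cond_du_ref)
    T_K <- celsius_to_kelvin(ch$T_C)
    K_h <- as.numeric(assoc_constant(ph, T_K))
    K_du <- as.numeric(assoc_constant(pdu, T_K))
    fr <- combined_fractions(K_h, K_du, ch$cond)
    if (share_folded)
      cbind(folded = fr$f_h + fr$f_du, unfolded = fr$f_un)
    else
      cbind(hairpin = fr$f_h, duplex = fr$f_du, unfolded = fr$f_un)
  }
}

#' Simultaneous combined-model fit of UV and NMR melting data
#'
#' Fits the coupled hairpin + homoduplex model (both species present) to a
#' UV score dataset and an NMR shift dataset recorded at very different
#' total strand concentrations.  A single set of hairpin and duplex
#' thermodynamic parameters drives the species fractions at each dataset's
#' concentration; every observable keeps linear state baselines (folded
#' hairpin and duplex strands share the folded baseline by default).  The
#' concentration contrast is what makes the duplex parameters
#' identifiable: with one method only, the fit is refused as not
#' separable.
#'
#' @param uv list(decomp =, M =, cond =, noise_sigma = optional
#'   per-point absorbance noise): a \code{factor_decomposition}, the
#'   number of score columns, and the UV conditions.  NULL to omit
#'   (raises the not-separable error).
#' @param nmr list(profiles =, cond =): shift profiles and NMR conditions.
#'   NULL to omit.
#' @param share_folded if TRUE (default) hairpin and duplex strands share
#'   one folded baseline per observable.
#' @return a \code{joint_fit_result} with hairpin_params, duplex_params,
#'   covariance of the nonlinear parameters, identifiability flag and the
#'   per-dataset duplex-fraction curves.
#' @export
fit_joint <- function(uv = NULL, nmr = NULL, share_folded = TRUE) {
  if (is.null(uv) || is.null(nmr))
    stop("not separable: the combined model needs both UV and NMR ",
         "datasets at different concentrations")
  ratio <- max(uv$cond$c, nmr$cond$c) / min(uv$cond$c, nmr$cond$c)
  if (ratio < 10)
    warning("concentrations differ by < 10x: duplex and hairpin ",
            "contributions may not be separable")
  # joint chi-square: every channel weighted by its own noise variance so
  # the two methods contribute on commensurate scales.  Score column j of
  # the SVD carries absorbance noise attenuated by 1/W_j, so its weight is
  # (W_j/sigma_A)^2 with sigma_A the per-point absorbance noise (taken
  # from the decomposition residual beyond M when not supplied).
  sigma_uv <- uv$noise_sigma
  if (is.null(sigma_uv)) {
    sigma_uv <- uv$decomp$residual_rms[uv$M + 1]
    if (sigma_uv <= 0) sigma_uv <- 1e-6
  }
  uv_channels <- lapply(seq_len(uv$M), function(j)
    .channel(uv$decomp$temperatures, uv$decomp$V[, j],
             w = rep((uv$decomp$W[j] / sigma_uv)^2, uv$decomp$n),
             label = sprintf("uv score%d", j), cond = uv$cond))
  nmr_channels <- lapply(nmr$profiles, function(p) {
    sig <- p$sigma
    if (is.null(sig)) {
      # noise from second differences of the trace
      s <- stats::sd(diff(p$delta, differences = 2)) / sqrt(6)
      sig <- rep(max(s, 1e-6), length(p$T_C))
    }
    .channel(p$T_C, p$delta, 1 / sig^2, label = p$nucleus, cond = nmr$cond)
  })
  channels <- c(uv_channels, nmr_channels)
  # seed the hairpin side from a hairpin-only fit of all channels
  pre <- .melt_fit(channels, "hairpin", nmr$cond)
  cond_du_ref <- equilibrium_conditions(nmr$cond$c, c_ref = nmr$cond$c_ref)
  pops <- .joint_pops(share_folded, cond_du_ref)
  tm_h <- pre$Tm_C
  dh_h <- pre$params$dH / 1000
  # theta = (Tm_h_C, dH_h kJ, Tm_du_C at the NMR concentration, dH_du kJ);
  # starts bracket duplex transitions near and below the hairpin Tm
  starts <- list(c(tm_h, dh_h, tm_h, -220),
                 c(tm_h, dh_h, tm_h - 10, -220),
                 c(tm_h, dh_h, tm_h - 25, -160),
                 c(tm_h, dh_h, tm_h + 5, -300),
                 c(tm_h, dh_h, tm_h - 40, -120))
  groups <- .make_groups(channels)
  best <- .fit_nonlinear(groups, pops, starts,
                         lower = c(-40, -2000, -40, -2000),
                         upper = c(150, -1, 150, -1))
  theta <- best$par
  sol <- .varpro_solve(theta, groups, pops)
  n_obs <- sum(vapply(channels, function(ch) length(ch$y), 0L))
  n_base <- (if (share_folded) 4L else 6L) * length(channels)
  dof <- max(n_obs - 4L - n_base, 1L)
  sigma2 <- best$value / dof
  cov_nl <- .nl_covariance(theta, groups, pops, sigma2)
  hairpin_params <- thermo_params_from_tm(theta[1], theta[2] * 1000,
                                          "hairpin", label = "hairpin")
  duplex_params <- thermo_params_from_tm(theta[3], theta[4] * 1000,
                                         "duplex", cond_du_ref,
                                         label = "homoduplex")
  se <- rep(NA_real_, 4)
  names(se) <- c("Tm_h_C", "dH_h", "Tm_du_C", "dH_du")
  identifiable <- FALSE
  if (!is.null(cov_nl)) {
    se[] <- sqrt(diag(cov_nl)) * c(1, 1000, 1, 1000)
    # duplex parameters count as identified when their relative standard
    # errors stay below 100% (Tm_du within +/- 20 degC)
    identifiable <- is.finite(se["dH_du"]) &&
      se["dH_du"] < abs(duplex_params$dH) &&
      is.finite(se["Tm_du_C"]) && se["Tm_du_C"] < 20
  }
  baselines <- do.call(rbind, lapply(seq_along(channels), function(i) {
    co <- sol[[i]]$coef
    data.frame(channel = channels[[i]]$label,
               t(stats::setNames(co, paste0("b", seq_along(co)))))
  }))
  structure(list(hairpin_params = hairpin_params,
                 duplex_params = duplex_params,
                 Tm_h_C = theta[1], Tm_du_C = theta[3],
                 cond_uv = uv$cond, cond_nmr = nmr$cond,
                 se = se, covariance = cov_nl, identifiable = identifiable,
                 rss = best$value, sigma2 = sigma2, n_obs = n_obs,
                 baselines = baselines, share_folded = share_folded,
                 convergence = best$convergence),
            class = "joint_fit_result")
}

#' @export
print.joint_fit_result <- function(x, ...) {
  cat("<joint_fit_result> combined hairpin + homoduplex model\n")
  cat(sprintf("  hairpin: Tm = %.2f degC, dH = %.1f kJ/mol, dS = %.1f J/mol/K\n",
              x$Tm_h_C, x$hairpin_params$dH / 1000, x$hairpin_params$dS))
  cat(sprintf("  duplex:  dH = %.1f kJ/mol, dS = %.1f J/mol/K (%sidentifiable)\n",
              x$duplex_params$dH / 1000, x$duplex_params$dS,
              if (x$identifiable) "" else "NOT "))
  cat(sprintf("  rss = %.4g over %d points\n", x$rss, x$n_obs))
  invisible(x)
}

#' Duplex strand fraction versus temperature from a joint fit
#'
#' Evaluates the combined-model species fractions on a temperature grid at
#' a given total strand concentration, using the fitted hairpin and duplex
#' parameters.
#'
#' @param res a \code{joint_fit_result}.
#' @param T_grid_C temperatures, degrees Celsius.
#' @param c total strand concentration, mol/L.
#' @param c_ref reference concentration, mol/L.
#' @return data frame (T_C, f_h, f_un, f_du).
#' @export
duplex_fraction_curve <- function(res, T_grid_C, c, c_ref = 1) {
  stopifnot(inherits(res, "joint_fit_result"))
  T_K <- celsius_to_kelvin(T_grid_C)
  K_h <- as.numeric(assoc_constant(res$hairpin_params, T_K))
  K_du <- as.numeric(assoc_constant(res$duplex_params, T_K))
  fr <- combined_fractions(K_h, K_du, equilibrium_conditions(c, c_ref = c_ref))
  cbind(data.frame(T_C = T_grid_C), fr)
}
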