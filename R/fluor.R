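#' A four-block fluorescence pattern
#'
#' The four spectra recorded per sample (FAM emission, FAM excitation,
#' Cy3 emission, Cy3 excitation) concatenated into one intensity vector
#' with recorded block boundaries and wavelength grids.
#'
#' @param sample sample name.
#' @param blocks named list of data frames (wavelength, intensity), one
#'   per spectral block, in a fixed order.
#' @return a \code{fluorescence_pattern} with fields \code{sample},
#'   \code{blocks}, \code{intensity} (concatenated vector) and
#'   \code{block_id}.
#' @export
fluorescence_pattern <- function(sample, blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1, !is.null(names(blocks)))
  for (b in blocks) {
    stopifnot(all(c("wavelength", "intensity") %in% names(b)))
    if (any(b$intensity < 0)) stop("negative intensities")
  }
  intensity <- unlist(lapply(blocks, `[[`, "intensity"), use.names = FALSE)
  block_id <- rep(names(blocks),
                  vapply(blocks, nrow, integer(1)))
  structure(list(sample = sample, blocks = blocks, intensity = intensity,
                 block_id = block_id),
            class = "fluorescence_pattern")
}

.same_grids <- function(a, b) {
  identical(names(a$blocks), names(b$blocks)) &&
    all(vapply(names(a$blocks), function(nm)
      isTRUE(all.equal(a$blocks[[nm]]$wavelength,
                       b$blocks[[nm]]$wavelength)), logical(1)))
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves min ||A x - b||^2 subject to x >= 0.  Small dense problems
#' only; used for spectral unmixing.
#'
#' @param A design matrix.
#' @param b response vector.
#' @param tol tolerance on the dual feasibility check.
#' @return list(x, fitted, residual_ss).
#' @export
nnls_fit <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A); b <- as.numeric(b)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  scale <- max(abs(w), 1)
  iter <- 0L
  while (any(!passive & w > tol * scale) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- drop(crossprod(A, b - A %*% x))
  }
  fitted <- drop(A %*% x)
  list(x = x, fitted = fitted, residual_ss = sum((b - fitted)^2))
}

#' Unmix a fluorescence pattern against reference patterns
#'
#' Non-negative least-squares decomposition of a measured pattern into
#' the supplied reference patterns (all on identical wavelength grids).
#' Weights are returned raw and normalized to fractions; a warning is
#' issued when the residual exceeds three times the supplied noise
#' estimate (pattern outside the reference span).
#'
#' @param pattern a \code{fluorescence_pattern}.
#' @param references list of >= 2 reference \code{fluorescence_pattern}.
#' @param noise_sigma optional per-channel noise standard deviation used
#'   for the residual warning.
#' @return list(weights, fractions, residual_rms).
#' @export
unmix_pattern <- function(pattern, references, noise_sigma = NULL) {
  stopifnot(length(references) >= 2)
  for (r in references)
    if (!.same_grids(pattern, r))
      stop("reference grid mismatch for sample ", r$sample)
  A <- vapply(references, `[[`, numeric(length(pattern$intensity)),
              "intensity")
  fit <- nnls_fit(A, pattern$intensity)
  wts <- fit$x
  names(wts) <- vapply(references, `[[`, character(1), "sample")
  rms <- sqrt(fit$residual_ss / length(pattern$intensity))
  if (!is.null(noise_sigma) && rms > 3 * noise_sigma)
    warning("unmixing residual ", signif(rms, 3),
            " exceeds 3x the noise estimate: pattern outside the ",
            "reference span?")
  list(weights = wts,
       fractions = if (sum(wts) > 0) wts / sum(wts) else wts,
       residual_rms = rms)
}

#' Fraction of labeled strands bound in heteroduplexes during a titration
#'
#' Competition equilibrium for a trace-labeled strand mixed with an
#' excess of unlabeled strand: the unlabeled pool equilibrates by the
#' combined hairpin + homoduplex model at its own concentration, giving
#' the free unfolded concentration u; the labeled strand then partitions
#' between hairpin (K_h), free coil, and heteroduplex with the unlabeled
#' strand (K' u), so f_du = K' u / (1 + K_h + K' u).  Labeled-labeled
#' duplexes are neglected (c_labeled << c_unlabeled).
#'
#' @param K_du duplex association constant, dimensionless on the c_ref
#'   scale (i.e. K_du[M^-1] when c_ref = 1 M).
#' @param K_h dimensionless hairpin association constant at the working
#'   temperature.
#' @param c_labeled,c_unlabeled concentrations, mol/L.
#' @param c_ref reference concentration, mol/L.
#' @return list(f_du, f_h, f_free) for the labeled strand.
#' @export
labeled_duplex_fraction <- function(K_du, K_h, c_labeled, c_unlabeled,
                                    c_ref = 1) {
  stopifnot(K_du >= 0, K_h >= 0, c_labeled >= 0, all(c_unlabeled >= 0))
  Kp <- K_du / c_ref
  u <- ifelse(c_unlabeled > 0,
              combined_fractions(K_h, K_du,
                                 equilibrium_conditions(
                                   pmax(c_unlabeled, .Machine$double.xmin),
                                   c_ref = c_ref))$f_un * c_unlabeled,
              0)
  den <- 1 + K_h + Kp * u
  list(f_du = Kp * u / den, f_h = K_h / den, f_free = 1 / den)
}

#' One titration point
#' @param c_labeled labeled strand concentration, mol/L (<= 1e-7 by
#'   design).
#' @param c_unlabeled unlabeled strand concentration, mol/L.
#' @param pattern the measured \code{fluorescence_pattern}.
#' @export
titration_point <- function(c_labeled, c_unlabeled, pattern) {
  stopifnot(c_labeled > 0, c_unlabeled >= 0)
  structure(list(c_labeled = c_labeled, c_unlabeled = c_unlabeled,
                 pattern = pattern), class = "titration_point")
}

#' Estimate the homoduplex association constant from a titration
#'
#' Each titration point is unmixed against the reference patterns; the
#' heteroduplex weight series is then fitted by weighted least squares
#' over K_du through \code{\link{labeled_duplex_fraction}} (K_h is
#' supplied, not refit).  The confidence interval comes from the profile
#' likelihood; a flat response returns an upper bound instead of a point
#' estimate.
#'
#' @param titration list of \code{titration_point} (>= 4, spanning >= 2
#'   decades of unlabeled concentration).
#' @param references list of reference \code{fluorescence_pattern}; the
#'   heteroduplex reference must be named \code{"duplex"}.
#' @param K_h dimensionless hairpin association constant at the working
#'   temperature.
#' @param c_ref reference concentration, mol/L.
#' @param conf confidence level of the profile-likelihood interval.
#' @return a \code{kdu_fit} with K_du (M^-1), K_du_uM (uM^-1), ci
#'   (bounds, M^-1), upper_bound_only flag, and the unmixed fraction
#'   series.
#' @export
fit_association_constant <- function(titration, references, K_h,
                                     c_ref = 1, conf = 0.95) {
  if (length(titration) < 4) stop("need >= 4 titration points")
  cu <- vapply(titration, `[[`, numeric(1), "c_unlabeled")
  pos <- cu[cu > 0]
  if (length(pos) >= 2 && diff(log10(range(pos))) < 2)
    warning("titration spans < 2 decades of unlabeled concentration")
  f_obs <- vapply(titration, function(tp)
    unmix_pattern(tp$pattern, references)$fractions[["duplex"]],
    numeric(1))
  cl <- vapply(titration, `[[`, numeric(1), "c_labeled")
  rss_of <- function(log10K) {
    f_mod <- vapply(seq_along(titration), function(i)
      labeled_duplex_fraction(10^log10K, K_h, cl[i], cu[i], c_ref)$f_du,
      numeric(1))
    sum((f_obs - f_mod)^2)
  }
  grid <- seq(0, 12, by = 0.25)
  vals <- vapply(grid, rss_of, numeric(1))
  g0 <- grid[which.min(vals)]
  opt <- stats::optimize(rss_of, c(g0 - 1, g0 + 1), tol = 1e-8)
  rss_min <- opt$objective
  n <- length(titration)
  K_est <- 10^opt$minimum
  # profile-likelihood interval: RSS(K) <= RSS_min (1 + chi2_1/(n - 1))
  thr <- rss_min * (1 + stats::qchisq(conf, 1) / max(n - 1, 1))
  fine <- seq(max(0, opt$minimum - 4), min(12, opt$minimum + 4), by = 0.02)
  prof <- vapply(fine, rss_of, numeric(1))
  inside <- fine[prof <= thr]
  ci <- if (length(inside)) 10^range(inside) else c(NA_real_, NA_real_)
  # flat response: K -> 0 is not rejected by the profile likelihood (or
  # the optimum sits at the grid floor), so only an upper bound is
  # supported
  upper_bound_only <- g0 <= min(grid) + 0.25 || rss_of(-6) <= thr
  if (upper_bound_only) ci[1] <- 0
  structure(list(K_du = if (upper_bound_only) NA_real_ else K_est,
                 K_du_uM = if (upper_bound_only) NA_real_ else K_est / 1e6,
                 upper_bound = ci[2], ci = ci,
                 upper_bound_only = upper_bound_only,
                 rss = rss_min, K_h = K_h,
                 series = data.frame(c_unlabeled = cu, c_labeled = cl,
                                     f_duplex = f_obs)),
            class = "kdu_fit")
}

#' @export
print.kdu_fit <- function(x, ...) {
  if (x$upper_bound_only)
    cat(sprintf("<kdu_fit> flat response: K_du < %.3g M^-1 (upper bound)\n",
                x$upper_bound))
  else
    cat(sprintf("<kdu_fit> K_du = %.3g M^-1 = %.2g uM^-1 (CI %.2g..%.2g M^-1)\n",
                x$K_du, x$K_du_uM, x$ci[1], x$ci[2]))
  invisible(x)
}
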