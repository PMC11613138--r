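#' A temperature-indexed spectral series
#'
#' @param wavelengths wavelength grid, nm (length p >= 2).
#' @param temperatures temperatures, degrees Celsius (length n >= 3).
#' @param Y n x p matrix of spectra, one row per temperature.
#' @param name,concentration,path_length metadata (concentration mol/L,
#'   path length cm).
#' @return a \code{spectral_series}.  Rows are sorted by temperature.
#' @export
spectral_series <- function(wavelengths, temperatures, Y, name = "series",
                            concentration = NA_real_, path_length = 1) {
  Y <- as.matrix(Y)
  if (anyNA(Y) || anyNA(wavelengths) || anyNA(temperatures))
    stop("NA values are not allowed in a spectral series")
  if (length(wavelengths) < 2 || length(temperatures) < 3)
    stop("need p >= 2 wavelengths and n >= 3 temperatures")
  if (nrow(Y) != length(temperatures) || ncol(Y) != length(wavelengths))
    stop("Y must be n_temperatures x n_wavelengths")
  if (anyDuplicated(temperatures)) stop("duplicate temperatures")
  o <- order(temperatures)
  structure(list(wavelengths = as.numeric(wavelengths),
                 temperatures = as.numeric(temperatures[o]),
                 Y = Y[o, , drop = FALSE], name = name,
                 concentration = concentration, path_length = path_length),
            class = "spectral_series")
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf("<spectral_series> %s: %d spectra (%.1f..%.1f degC) x %d wavelengths (%.0f..%.0f nm)\n",
              x$name, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Factor analysis of a spectral series by singular value decomposition
#'
#' Decomposes the n x p series Y into Y = V diag(W) S, with orthonormal
#' spectral profiles in the rows of S, orthonormal score columns in V, and
#' non-negative singular values W in descending order.  A deterministic
#' sign convention is applied: each profile is oriented so that its
#' largest-magnitude element is positive, with the sign absorbed into the
#' scores.
#'
#' @param series a \code{spectral_series}.
#' @return a \code{factor_decomposition} with fields \code{S} (r x p
#'   profile rows), \code{V} (n x r scores), \code{W} (singular values),
#'   \code{residual_rms} (rms truncation residual for M = 0..r),
#'   \code{temperatures}, \code{wavelengths}.
#' @export
decompose <- function(series) {
  stopifnot(inherits(series, "spectral_series"))
  Y <- series$Y
  sv <- svd(Y)
  r <- length(sv$d)
  # sign convention: largest-|.| element of each profile positive
  S <- t(sv$v)                      # r x p
  V <- sv$u                         # n x r
  for (j in seq_len(r)) {
    k <- which.max(abs(S[j, ]))
    if (S[j, k] < 0) {
      S[j, ] <- -S[j, ]
      V[, j] <- -V[, j]
    }
  }
  np <- length(Y)
  resid <- sqrt(rev(cumsum(rev(sv$d^2)))/np)  # rms residual after M-1 terms
  residual_rms <- c(resid, 0)                 # index M+1 -> residual at M
  structure(list(S = S, V = V, W = sv$d, residual_rms = residual_rms,
                 temperatures = series$temperatures,
                 wavelengths = series$wavelengths,
                 n = nrow(Y), p = ncol(Y), name = series$name),
            class = "factor_decomposition")
}

#' @export
print.factor_decomposition <- function(x, ...) {
  cat(sprintf("<factor_decomposition> %s: n = %d, p = %d\n", x$name, x$n, x$p))
  cat("  W/W1:", paste(signif(x$W / x$W[1], 3)[seq_len(min(6, length(x$W)))],
                       collapse = " "), "\n")
  invisible(x)
}

#' Lag-1 autocorrelation of a score column
#' @noRd
.lag1_autocor <- function(v) {
  v <- v - mean(v)
  den <- sum(v^2)
  if (den == 0) return(0)
  sum(v[-1] * v[-length(v)]) / den
}

#' Estimate the factor dimension of a decomposition
#'
#' The factor dimension M is the number of spectral components needed to
#' reproduce the series within experimental error.  Component j is counted
#' as significant when all three hold: (i) its singular value is at least
#' one per mille of the first, W_j/W_1 >= 1e-3; (ii) the truncation
#' residual with j-1 components still exceeds the noise floor; and
#' (iii) its score column varies smoothly with temperature (lag-1
#' autocorrelation >= 0.5) rather than erratically.  M is the largest j
#' passing all three; at least 1 is returned.
#'
#' When \code{noise_sigma} is not supplied the noise floor is estimated
#' from the tail singular values: the median of the smallest
#' \code{max(2, n - 6)} values divided by sqrt(max(n, p)) (a root-n*p
#' style heuristic for i.i.d. Gaussian noise; override with the known
#' per-point sigma when available).
#'
#' @param decomp a \code{factor_decomposition}.
#' @param noise_sigma per-point noise standard deviation in the units of
#'   the spectra, or NULL to estimate from the tail singular values.
#' @param w_ratio_min,score_smooth_min thresholds of criteria (i) and
#'   (iii).
#' @return integer M >= 1, with attribute \code{criteria} (logical matrix).
#' @export
estimate_dimension <- function(decomp, noise_sigma = NULL,
                               w_ratio_min = 1e-3, score_smooth_min = 0.5) {
  stopifnot(inherits(decomp, "factor_decomposition"))
  W <- decomp$W
  r <- length(W)
  n <- decomp$n; p <- decomp$p
  if (is.null(noise_sigma)) {
    ntail <- max(2L, n - 6L)
    tail_w <- sort(W)[seq_len(min(ntail, r))]
    noise_sigma <- stats::median(tail_w) / sqrt(max(n, p))
  }
  crit <- matrix(FALSE, r, 3,
                 dimnames = list(NULL, c("weight", "residual", "smooth")))
  crit[, "weight"] <- W / W[1] >= w_ratio_min
  # residual_rms[j] is the rms residual of the (j-1)-component truncation
  crit[, "residual"] <- decomp$residual_rms[seq_len(r)] > noise_sigma
  crit[, "smooth"] <- apply(decomp$V, 2, .lag1_autocor) >= score_smooth_min
  ok <- which(rowSums(crit) == 3)
  M <- if (length(ok)) max(ok) else 1L
  attr(M, "criteria") <- crit
  attr(M, "noise_sigma") <- noise_sigma
  M
}

#' Reconstruct a spectral series from the leading M components
#'
#' @param decomp a \code{factor_decomposition}.
#' @param M number of components, 1 <= M <= rank.
#' @return a \code{spectral_series}; the rms residual versus the full data
#'   is attached as attribute \code{residual_rms}.
#' @export
reconstruct <- function(decomp, M) {
  stopifnot(inherits(decomp, "factor_decomposition"))
  r <- length(decomp$W)
  if (length(M) != 1 || M < 1 || M > r) stop("M out of range 1..", r)
  idx <- seq_len(M)
  Y <- decomp$V[, idx, drop = FALSE] %*%
    (decomp$W[idx] * decomp$S[idx, , drop = FALSE])
  out <- spectral_series(decomp$wavelengths, decomp$temperatures, Y,
                         name = sprintf("%s (M=%d)", decomp$name, M))
  attr(out, "residual_rms") <- decomp$residual_rms[M + 1]
  out
}
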