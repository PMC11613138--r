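#' Molar gas constant, J mol-1 K-1
#' @export
R_GAS <- 8.314

#' Celsius/Kelvin conversion helpers
#' @param T_C temperature in degrees Celsius.
#' @return temperature in Kelvin.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' @rdname celsius_to_kelvin
#' @param T_K temperature in Kelvin.
#' @export
kelvin_to_celsius <- function(T_K) T_K - 273.15

#' Thermodynamic parameters of an association step
#'
#' Association convention throughout: K = folded/unfolded, so folding has
#' dH < 0 and dS < 0.  Units are J/mol and J/(mol K).
#'
#' @param dH enthalpy change of association, J/mol.
#' @param dS entropy change of association, J/(mol K).
#' @param label optional text label.
#' @export
thermo_params <- function(dH, dS, label = "") {
  stopifnot(is.finite(dH), is.finite(dS))
  structure(list(dH = dH, dS = dS, label = label), class = "thermo_params")
}

#' Thermodynamic parameters from a melting temperature and enthalpy
#'
#' The (Tm, dH) parameterization used internally for conditioning.  For a
#' unimolecular (hairpin) transition Tm = dH/dS; for a bimolecular duplex
#' at total strand concentration c, Tm solves K(Tm) = c_ref/c, i.e.
#' dS = dH/Tm - R log(c/c_ref).
#'
#' @param Tm_C melting temperature, degrees Celsius.
#' @param dH association enthalpy, J/mol.
#' @param model "hairpin" or "duplex".
#' @param cond an \code{equilibrium_conditions} (required for "duplex").
#' @param label optional text label.
#' @export
thermo_params_from_tm <- function(Tm_C, dH, model = c("hairpin", "duplex"),
                                  cond = NULL, label = "") {
  model <- match.arg(model)
  Tm <- celsius_to_kelvin(Tm_C)
  dS <- if (model == "hairpin") dH / Tm
        else {
          stopifnot(!is.null(cond))
          dH / Tm - R_GAS * log(cond$c / cond$c_ref)
        }
  thermo_params(dH, dS, label)
}

#' Solution conditions for the equilibria
#'
#' @param c total strand concentration, mol/L (one strand = one molecule).
#' @param T_C temperature, degrees Celsius (optional, may be supplied per
#'   call).
#' @param c_ref reference concentration, mol/L (default 1).
#' @export
equilibrium_conditions <- function(c, T_C = NA_real_, c_ref = 1) {
  stopifnot(c > 0, c_ref > 0)
  structure(list(c = c, T_C = T_C, c_ref = c_ref),
            class = "equilibrium_conditions")
}

#' Van't Hoff association constant
#'
#' K(T) = exp(-(dH - T dS)/(R T)); the Gibbs free energy dG = dH - T dS is
#' returned as an attribute.
#'
#' @param params a \code{thermo_params}.
#' @param T_K temperature(s) in Kelvin.
#' @return dimensionless K with attribute \code{dG} (J/mol).
#' @export
assoc_constant <- function(params, T_K) {
  stopifnot(all(T_K > 0))
  dG <- params$dH - T_K * params$dS
  K <- exp(-dG / (R_GAS * T_K))
  attr(K, "dG") <- dG
  K
}

#' Species fractions when only hairpins form (model i)
#'
#' @param K_h dimensionless hairpin association constant(s).
#' @return data frame with f_h, f_un, f_du (f_du = 0).
#' @export
hairpin_fractions <- function(K_h) {
  stopifnot(all(K_h >= 0))
  data.frame(f_h = K_h / (1 + K_h), f_un = 1 / (1 + K_h),
             f_du = 0 * K_h)
}

#' Species fractions when only duplexes form (model ii)
#'
#' With K' = K_du/c_ref the mass balance 2 K' c_un^2 + c_un - c = 0 is
#' solved by the cancellation-safe root c_un = 2c/(1 + sqrt(1 + 8 K' c)).
#' f_du = 2 c_du / c counts strands in duplexes.
#'
#' @param K_du dimensionless duplex association constant(s).
#' @param cond an \code{equilibrium_conditions}.
#' @export
duplex_fractions <- function(K_du, cond) {
  stopifnot(all(K_du >= 0))
  Kp <- K_du / cond$c_ref
  c_un <- 2 * cond$c / (1 + sqrt(1 + 8 * Kp * cond$c))
  data.frame(f_h = 0 * K_du, f_un = c_un / cond$c,
             f_du = 1 - c_un / cond$c)
}

#' Species fractions when both hairpins and duplexes form (model iii)
#'
#' Mass balance c = c_un + c_h + 2 c_du with c_h = K_h c_un and
#' c_du = (K_du/c_ref) c_un^2 gives the quadratic
#' 2 K' c_un^2 + (1 + K_h) c_un - c = 0, solved by the cancellation-safe
#' positive root.
#'
#' @param K_h,K_du dimensionless association constants (vectorized).
#' @param cond an \code{equilibrium_conditions}.
#' @return data frame with columns f_h, f_un, f_du summing to 1.
#' @export
combined_fractions <- function(K_h, K_du, cond) {
  stopifnot(all(K_h >= 0), all(K_du >= 0))
  Kp <- K_du / cond$c_ref
  b <- 1 + K_h
  c_un <- 2 * cond$c / (b + sqrt(b^2 + 8 * Kp * cond$c))
  f_un <- c_un / cond$c
  f_h <- K_h * f_un
  data.frame(f_h = f_h, f_un = f_un, f_du = 1 - f_un - f_h)
}

#' Melting temperature of a two-state transition
#'
#' Unimolecular (hairpin): Tm = dH/dS, independent of concentration.
#' Bimolecular (duplex): Tm solves K_du(Tm) = c_ref/c, i.e.
#' Tm = dH/(dS + R log(c/c_ref)), shifting with concentration.
#'
#' @param params a \code{thermo_params}.
#' @param model "hairpin" or "duplex".
#' @param cond an \code{equilibrium_conditions} (required for "duplex").
#' @return Tm in Kelvin.
#' @export
melting_temperature <- function(params, model = c("hairpin", "duplex"),
                                cond = NULL) {
  model <- match.arg(model)
  if (model == "hairpin") {
    if (params$dS == 0 || params$dH / params$dS <= 0)
      stop("no physical Tm: dS zero or dH/dS not positive")
    return(params$dH / params$dS)
  }
  stopifnot(!is.null(cond))
  den <- params$dS + R_GAS * log(cond$c / cond$c_ref)
  if (den == 0 || params$dH / den <= 0)
    stop("no physical Tm: denominator sign inconsistent with dH")
  params$dH / den
}
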