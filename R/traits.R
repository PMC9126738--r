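#' Stomatal limitation from a fitted A/ci curve
#'
#' The proportional reduction of assimilation attributable to stomata:
#' L_s = (A0 - A_op) / A0, where A0 is the fitted net assimilation the leaf
#' would attain with infinite stomatal conductance, i.e. the fitted model
#' evaluated at ci = ca, and A_op the observed operating assimilation.
#'
#' @param fit an `aci_fit` from [fit_aci()].
#' @param op operating point: list/row with `ci_op`, `A_op`, `ca` (see
#'   [operating_point()]).
#' @param k kinetic constants used in the fit.
#' @return L_s (dimensionless); 0 <= L_s < 1 when A_op < A0.
#' @export
stomatal_limitation <- function(fit, op, k = wheat_constants()) {
  k <- resolve_constants(k)
  stopifnot(fit$ok)
  A0 <- net_assimilation(op$ca, fit$params, k, T_leaf = fit$T_leaf,
                         states = fit$present)$A
  if (A0 <= 0) stop("stomatal limitation undefined: reference assimilation A0 <= 0")
  (A0 - op$A_op) / A0
}

#' Operating point of a gas-exchange log
#'
#' Extracts the steady-state operating point, by default the observation
#' logged immediately before the CO2 ramp (lowest `sequence_index`),
#' configurable to any row.
#'
#' @param curve an [aci_curve()].
#' @param row row index in acquisition order; default 1 (pre-ramp steady
#'   state).
#' @return list with `ci_op`, `A_op`, `gs_op`, `ca`, `Q`.
#' @export
operating_point <- function(curve, row = 1) {
  i <- order(curve$sequence_index)[row]
  list(ci_op = curve$ci[i], A_op = curve$A[i], gs_op = curve$gs[i],
       ca = curve$ca[i], Q = curve$Q[i])
}

#' Intrinsic water-use efficiency
#'
#' iWUE = A / g_s, in µmol CO2 mol-1 H2O; `gs` must be in mol m-2 s-1.
#'
#' @param A net assimilation (µmol m-2 s-1).
#' @param gs stomatal conductance (mol m-2 s-1), > 0.
#' @return iWUE (µmol mol-1); vectorized.
#' @export
iwue <- function(A, gs) {
  if (any(gs <= 0)) stop("iwue undefined for gs <= 0")
  A / gs
}

#' J to Vcmax ratio
#'
#' Ratio of electron transport rate to maximum carboxylation rate at a
#' common reference temperature. Accepts either an `aci_fit` (uses the
#' 25 degC-normalized rates) or two numbers.
#'
#' @param J electron transport rate, or an `aci_fit`.
#' @param Vcmax maximum carboxylation rate (ignored when `J` is a fit).
#' @return dimensionless ratio.
#' @export
j_v_ratio <- function(J, Vcmax = NULL) {
  if (inherits(J, "aci_fit")) {
    stopifnot(J$ok)
    return(J$params_25$J25 / J$params_25$Vcmax25)
  }
  J / Vcmax
}

#' Per-nitrogen normalization
#'
#' Divides an area-based trait (µmol m-2 s-1) by leaf nitrogen per area
#' (g N m-2), yielding µmol s-1 (g N)-1.
#'
#' @param value trait value(s), µmol m-2 s-1.
#' @param Narea leaf nitrogen content per area (g N m-2), > 0.
#' @return value / Narea; vectorized.
#' @export
per_nitrogen <- function(value, Narea) {
  if (any(Narea <= 0)) stop("per_nitrogen undefined for Narea <= 0")
  value / Narea
}

#' Yield-component identities
#'
#' Grains per square metre GM2 = (GY / TGW) x 1000 and total above-ground
#' biomass at physiological maturity = GY / HI.
#'
#' @param GY grain yield (g m-2).
#' @param TGW thousand-grain weight (g), > 0.
#' @param HI harvest index, in (0, 1].
#' @return data.frame with `GM2` (grains m-2) and `biomass` (g m-2);
#'   vectorized.
#' @export
yield_components <- function(GY, TGW, HI) {
  if (any(TGW <= 0)) stop("TGW must be > 0")
  if (any(HI <= 0 | HI > 1)) stop("HI must be in (0, 1]")
  data.frame(GM2 = (GY / TGW) * 1000, biomass = GY / HI)
}

#' Operating and light-saturated assimilation from a light-response table
#'
#' Extracts A at the PAR set-points 500 (operational rate, A_op) and 1800
#' (saturating rate, A_sat) µmol m-2 s-1 by nearest-set-point matching
#' within a relative tolerance.
#'
#' @param light_curve data.frame with columns `Q` (PAR) and `A`.
#' @param tol relative matching tolerance (default 0.10).
#' @return list with `A_op` and `A_sat`; `NA` where the set-point is
#'   missing.
#' @export
operating_rates <- function(light_curve, tol = 0.10) {
  pick <- function(target) {
    d <- abs(light_curve$Q - target)
    i <- which.min(d)
    if (length(i) == 0 || d[i] > tol * target) NA_real_ else light_curve$A[i]
  }
  list(A_op = pick(500), A_sat = pick(1800))
}

#' Leaf composition consistency checks
#'
#' Validates a leaf-composition record: Rubisco activation state =
#' initial/total activity x 100 must lie in (0, 150], and
#' Nmass = 1000 * Narea / LMA within 1 percent when all three are present.
#'
#' @param comp list or one-row data.frame with any of `Narea` (g m-2),
#'   `Nmass` (mg g-1), `LMA` (g m-2), `initial_activity`, `total_activity`.
#' @return list with `activation_state` (percent, or NA) and `consistent`
#'   (logical).
#' @export
leaf_composition_check <- function(comp) {
  act <- NA_real_
  if (!is.null(comp$initial_activity) && !is.null(comp$total_activity) &&
      is.finite(comp$initial_activity) && is.finite(comp$total_activity)) {
    act <- comp$initial_activity / comp$total_activity * 100
    if (act <= 0 || act > 150) stop("activation state outside (0, 150]%")
  }
  consistent <- TRUE
  if (all(c("Narea", "Nmass", "LMA") %in% names(comp)) &&
      all(is.finite(c(comp$Narea, comp$Nmass, comp$LMA)))) {
    expected <- 1000 * comp$Narea / comp$LMA
    consistent <- abs(comp$Nmass - expected) <= 0.01 * expected
  }
  list(activation_state = act, consistent = consistent)
}
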