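GM_INFINITE <- 1e6  # µmol m-2 s-1 Pa-1; "infinite" mesophyll conductance

#' FvCB parameter set
#'
#' Bundles the biochemical parameters of the Farquhar-von Caemmerer-Berry
#' model of C3 net CO2 assimilation: maximum Rubisco carboxylation rate
#' `Vcmax`, electron transport rate `J`, triose-phosphate utilization rate
#' `Tp` (optional; `NA` means the TPU limitation is not modelled), day
#' respiration `Rd` (all µmol m-2 s-1), and a mesophyll-conductance mode.
#'
#' The RuBP-regeneration branch uses the NADPH-limited electron stoichiometry
#' A_J = J (c - GammaStar) / (j_c * c + j_g * GammaStar) - Rd with
#' (j_c, j_g) = (4, 8) by default; the ATP-limited alternative (4.5, 10.5)
#' can be selected. The TPU branch is the simple form A_P = 3 Tp - Rd,
#' constant in c (no glycolate-export term).
#'
#' @param Vcmax maximum carboxylation rate (µmol m-2 s-1).
#' @param J electron transport rate (µmol m-2 s-1).
#' @param Tp triose-phosphate utilization rate (µmol m-2 s-1) or `NA`.
#' @param Rd day respiration (µmol m-2 s-1).
#' @param gm_mode one of "infinite", "fixed", "fitted".
#' @param gm mesophyll conductance (µmol m-2 s-1 Pa-1); forced to 1e6 when
#'   `gm_mode = "infinite"`.
#' @param T_ref temperature the rates refer to (degC).
#' @param j_stoich electron-transport stoichiometry, "nadph" (4c + 8G*) or
#'   "atp" (4.5c + 10.5G*).
#' @return An object of class `fvcb_params`.
#' @export
fvcb_params <- function(Vcmax, J, Tp = NA_real_, Rd,
                        gm_mode = c("infinite", "fixed", "fitted"),
                        gm = GM_INFINITE, T_ref = 25,
                        j_stoich = c("nadph", "atp")) {
  gm_mode <- match.arg(gm_mode)
  j_stoich <- match.arg(j_stoich)
  if (gm_mode == "infinite") gm <- GM_INFINITE
  stopifnot(Vcmax > 0, J > 0, is.na(Tp) || Tp > 0, gm > 0, is.finite(Rd))
  structure(list(Vcmax = Vcmax, J = J, Tp = Tp, Rd = Rd,
                 gm_mode = gm_mode, gm = gm, T_ref = T_ref,
                 j_stoich = j_stoich,
                 jc = if (j_stoich == "nadph") 4 else 4.5,
                 jg = if (j_stoich == "nadph") 8 else 10.5),
            class = "fvcb_params")
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat(sprintf("FvCB parameters at %.1f degC (gm_mode = %s):\n", x$T_ref, x$gm_mode))
  cat(sprintf("  Vcmax = %.2f  J = %.2f  Tp = %s  Rd = %.3f µmol m-2 s-1\n",
              x$Vcmax, x$J, if (is.na(x$Tp)) "absent" else sprintf("%.2f", x$Tp),
              x$Rd))
  if (x$gm_mode != "infinite")
    cat(sprintf("  gm = %.3f µmol m-2 s-1 Pa-1\n", x$gm))
  invisible(x)
}

#' Limitation-branch assimilation rates
#'
#' Net CO2 assimilation on each FvCB limitation branch evaluated at a CO2
#' partial pressure `c` (chloroplastic, or intercellular under infinite
#' mesophyll conductance). `rate_rubisco` is the Rubisco- (RuBP-saturated)
#' limited rate, `rate_rubp` the RuBP-regeneration (electron-transport)
#' limited rate, and `rate_tpu` the triose-phosphate-utilization limited
#' rate, which is independent of `c`.
#'
#' @param c CO2 partial pressure (Pa), >= 0; vectorized.
#' @param p an [fvcb_params()] object.
#' @param k a `kinetic_constants` object.
#' @param T_leaf leaf temperature (degC) at which Kc, Ko, GammaStar are
#'   evaluated; defaults to `p$T_ref`.
#' @return Net assimilation (µmol m-2 s-1); may be negative below the
#'   compensation point.
#' @export
rate_rubisco <- function(c, p, k, T_leaf = p$T_ref) {
  stopifnot(all(c >= 0))
  kt <- kinetics_at(k, T_leaf)
  p$Vcmax * (c - kt$GammaStar) / (c + kt$Km) - p$Rd
}

#' @rdname rate_rubisco
#' @export
rate_rubp <- function(c, p, k, T_leaf = p$T_ref) {
  stopifnot(all(c >= 0))
  kt <- kinetics_at(k, T_leaf)
  p$J * (c - kt$GammaStar) / (p$jc * c + p$jg * kt$GammaStar) - p$Rd
}

#' @rdname rate_rubisco
#' @export
rate_tpu <- function(p) {
  if (is.na(p$Tp)) stop("TPU limitation state not available: Tp is absent")
  3 * p$Tp - p$Rd
}

# Ethier-style quadratic for one hyperbolic branch under finite gm:
# A = [p_ - sqrt(p_^2 - 4 q)]/2 where the drawdown is cc = ci - A/gm.
# x1 = Vcmax (with x2 = Km) or J/jc (with x2 = jg*GammaStar/jc).
branch_quadratic <- function(ci, x1, x2, GammaStar, Rd, gm) {
  p_ <- gm * (ci + x2) + x1 - Rd
  q_ <- gm * (x1 * (ci - GammaStar) - Rd * (ci + x2))
  disc <- p_^2 - 4 * q_
  if (any(disc < 0)) stop("infeasible parameters: negative discriminant in mesophyll drawdown quadratic")
  (p_ - sqrt(disc)) / 2
}

#' Net assimilation under the minimum rule
#'
#' Evaluates the FvCB model at intercellular CO2 `ci`: each available
#' limitation branch is solved self-consistently with the mesophyll
#' drawdown cc = ci - A/gm (analytic per-branch quadratic; with
#' `gm_mode = "infinite"` this reduces to evaluating the branches at `ci`),
#' and the minimum is taken. Branches within `tol_colimit` of the minimum
#' are reported as co-limited.
#'
#' @inheritParams rate_rubisco
#' @param ci intercellular CO2 partial pressure (Pa); vectorized.
#' @param states character vector of branches to consider, subset of
#'   c("C", "J", "P").
#' @param tol_colimit tie tolerance for the co-limited label
#'   (µmol m-2 s-1).
#' @return A data.frame with columns `ci`, `A` (µmol m-2 s-1), `state`
#'   ("C", "J" or "P"), `colimited` (logical).
#' @export
net_assimilation <- function(ci, p, k, T_leaf = p$T_ref,
                             states = c("C", "J", "P"),
                             tol_colimit = 1e-6) {
  stopifnot(all(ci >= 0), length(states) >= 1)
  states <- match.arg(states, c("C", "J", "P"), several.ok = TRUE)
  if (is.na(p$Tp)) states <- setdiff(states, "P")
  if (length(states) == 0) stop("no available limitation states")
  kt <- kinetics_at(k, T_leaf)
  rates <- matrix(NA_real_, nrow = length(ci), ncol = length(states),
                  dimnames = list(NULL, states))
  for (s in states) {
    rates[, s] <- switch(s,
      C = branch_quadratic(ci, p$Vcmax, kt$Km, kt$GammaStar, p$Rd, p$gm),
      J = branch_quadratic(ci, p$J / p$jc, p$jg * kt$GammaStar / p$jc,
                           kt$GammaStar, p$Rd, p$gm),
      P = rep(rate_tpu(p), length(ci)))
  }
  A <- apply(rates, 1, min)
  idx <- apply(rates, 1, which.min)
  colim <- vapply(seq_along(ci), function(i)
    sum(rates[i, ] - A[i] < tol_colimit) > 1, logical(1))
  data.frame(ci = ci, A = A, state = states[idx], colimited = colim,
             stringsAsFactors = FALSE)
}

#' Limitation-transition and compensation points
#'
#' Closed-form intersection points of the FvCB branches under infinite
#' mesophyll conductance (for finite gm the transition is located
#' numerically on the ci axis). `transition_ci_cJ` is the ci at which
#' limitation passes from Rubisco to RuBP regeneration,
#' ci_cJ = (J Km - jg GammaStar Vcmax) / (jc Vcmax - J);
#' `transition_ci_JP` the ci of the RuBP-regeneration-to-TPU transition,
#' ci_JP = GammaStar (J + 3 jg Tp) / (J - 3 jc Tp); and
#' `compensation_point` the observed compensation point on the Rubisco
#' branch, Gamma = (GammaStar Vcmax + Rd Km) / (Vcmax - Rd).
#'
#' With the default stoichiometry (jc, jg) = (4, 8) these are the familiar
#' (J Km - 8 G* Vcmax)/(4 Vcmax - J) and G*(J + 24 Tp)/(J - 12 Tp).
#'
#' @inheritParams rate_rubisco
#' @return ci (or Gamma) in Pa; `NA` when the transition does not exist
#'   (non-physical, i.e. <= GammaStar, or TPU never limiting).
#' @export
transition_ci_cJ <- function(p, k, T_leaf = p$T_ref) {
  kt <- kinetics_at(k, T_leaf)
  if (p$gm_mode != "infinite" && p$gm < GM_INFINITE)
    return(transition_numeric(p, k, T_leaf, "C", "J"))
  denom <- p$jc * p$Vcmax - p$J
  if (abs(denom) < 1e-12) return(NA_real_)
  ci <- (p$J * kt$Km - p$jg * kt$GammaStar * p$Vcmax) / denom
  if (!is.finite(ci) || ci <= kt$GammaStar) NA_real_ else ci
}

#' @rdname transition_ci_cJ
#' @export
transition_ci_JP <- function(p, k, T_leaf = p$T_ref) {
  if (is.na(p$Tp)) return(NA_real_)
  kt <- kinetics_at(k, T_leaf)
  if (p$J <= 3 * p$jc * p$Tp) return(NA_real_)  # TPU never limiting
  if (p$gm_mode != "infinite" && p$gm < GM_INFINITE)
    return(transition_numeric(p, k, T_leaf, "J", "P"))
  kt$GammaStar * (p$J + 3 * p$jg * p$Tp) / (p$J - 3 * p$jc * p$Tp)
}

#' @rdname transition_ci_cJ
#' @export
compensation_point <- function(p, k, T_leaf = p$T_ref) {
  kt <- kinetics_at(k, T_leaf)
  if (p$Vcmax <= p$Rd) stop("no compensation point: Vcmax <= Rd")
  (kt$GammaStar * p$Vcmax + p$Rd * kt$Km) / (p$Vcmax - p$Rd)
}

# Numeric transition for finite gm: root of branch-rate difference on ci.
transition_numeric <- function(p, k, T_leaf, s1, s2, upper = 500) {
  kt <- kinetics_at(k, T_leaf)
  rate_of <- function(s, ci) switch(s,
    C = branch_quadratic(ci, p$Vcmax, kt$Km, kt$GammaStar, p$Rd, p$gm),
    J = branch_quadratic(ci, p$J / p$jc, p$jg * kt$GammaStar / p$jc,
                         kt$GammaStar, p$Rd, p$gm),
    P = rate_tpu(p))
  f <- function(ci) rate_of(s1, ci) - rate_of(s2, ci)
  lo <- kt$GammaStar + 1e-6
  if (f(lo) * f(upper) > 0) return(NA_real_)
  stats::uniroot(f, c(lo, upper), tol = 1e-10)$root
}
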