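#' Enumerate ordered limitation-state assignments
#'
#' All contiguous assignments of `n` observations (sorted by ci) to the
#' limitation states in their required order along the ci axis
#' (Rubisco "C" < RuBP regeneration "J" < TPU "P"), any state possibly
#' absent, each present state covering at least `min_per_state`
#' observations. Single-state assignments are included. Order is
#' deterministic: state subsets in the fixed sequence C, J, P, CJ, CP, JP,
#' CJP, then lexicographic by split positions within a subset.
#'
#' @param n observation count.
#' @param states subset of c("C", "J", "P") allowed in assignments.
#' @param min_per_state minimum observations per present state.
#' @return A list of character vectors of length `n`.
#' @export
enumerate_assignments <- function(n, states = c("C", "J", "P"),
                                  min_per_state = 2) {
  if (length(states) == 0) stop("empty state set")
  states <- match.arg(states, c("C", "J", "P"), several.ok = TRUE)
  if (n < min_per_state) stop("n < min_per_state")
  states <- c("C", "J", "P")[c("C", "J", "P") %in% states]
  subsets <- list()
  for (size in seq_along(states))
    subsets <- c(subsets, utils::combn(states, size, simplify = FALSE))
  out <- list()
  for (sub in subsets) {
    k <- length(sub)
    if (n < k * min_per_state) next
    for (counts in compositions(n, k, min_per_state))
      out[[length(out) + 1L]] <- rep(sub, times = counts)
  }
  out
}

# All ordered compositions of n into k parts each >= m, lexicographic.
compositions <- function(n, k, m) {
  if (k == 1) return(if (n >= m) list(n) else list())
  out <- list()
  for (first in m:(n - m * (k - 1))) {
    for (rest in compositions(n - first, k - 1, m))
      out[[length(out) + 1L]] <- c(first, rest)
  }
  out
}

# Regressors of the linearized (gm-infinite) branch models at sorted ci.
branch_regressors <- function(ci, kt, jc, jg) {
  list(C = (ci - kt$GammaStar) / (ci + kt$Km),
       J = (ci - kt$GammaStar) / (jc * ci + jg * kt$GammaStar),
       P = rep(3, length(ci)))
}

#' Fit FvCB parameters for one limitation-state assignment
#'
#' Estimates the parameters of the states present in `assignment` (Vcmax
#' for "C", J for "J", Tp for "P") plus the shared day respiration Rd by
#' minimizing the summed squared residuals of the assigned branch models.
#' Under `gm_mode = "infinite"` every branch is linear in its parameters,
#' so the exact least-squares solution is computed in closed form; under
#' finite or fitted mesophyll conductance the per-branch drawdown
#' quadratic makes the problem nonlinear and a deterministic multi-start
#' Nelder-Mead search (seeded from the infinite-gm solution and a fixed
#' parameter grid) is used.
#'
#' @param curve an [aci_curve()] (observations are sorted by ci
#'   internally).
#' @param assignment character vector, one of "C","J","P" per sorted
#'   observation.
#' @param k a `kinetic_constants` object (or name, see
#'   [wheat_constants()]).
#' @param gm_mode "infinite", "fixed" or "fitted".
#' @param gm mesophyll conductance (µmol m-2 s-1 Pa-1) when
#'   `gm_mode = "fixed"`.
#' @param j_stoich electron-transport stoichiometry passed to
#'   [fvcb_params()].
#' @return An object of class `aci_fit`: list with `params` (at the curve
#'   mean leaf temperature), `params_25` (Vcmax, J, Rd normalized to 25
#'   degC; Tp reported unnormalized), `assignment` (in ci order), `order`
#'   (permutation sorting the curve by ci), `cost` (sum of squared
#'   residuals), `ok` (parameters identifiable, positive rates, optimizer
#'   converged), `rd_positive`, `admissible` (`NA` until checked),
#'   `transitions` (ci_cJ, ci_JP, Pa or NA), `fitted` (per-observation
#'   model values), `n_swing_reassignments`, `constants_label`, `gm_mode`.
#' @export
fit_assignment <- function(curve, assignment, k = wheat_constants(),
                           gm_mode = c("infinite", "fixed", "fitted"),
                           gm = 5.5, j_stoich = "nadph") {
  gm_mode <- match.arg(gm_mode)
  k <- resolve_constants(k)
  ord <- order(curve$ci)
  ci <- curve$ci[ord]; A <- curve$A[ord]
  n <- length(ci)
  stopifnot(length(assignment) == n)
  present <- c("C", "J", "P")[c("C", "J", "P") %in% unique(assignment)]
  Tm <- mean_t_leaf(curve)
  kt <- kinetics_at(k, Tm)
  jc <- if (j_stoich == "nadph") 4 else 4.5
  jg <- if (j_stoich == "nadph") 8 else 10.5
  n_par <- length(present) + 1 + (gm_mode == "fitted")
  if (n < n_par + 1)
    stop(sprintf("assignment needs >= %d observations for %d parameters", n_par + 1, n_par))

  # closed-form linear solution under infinite gm (also seeds finite-gm search)
  reg <- branch_regressors(ci, kt, jc, jg)
  X <- cbind(vapply(present, function(s) ifelse(assignment == s, reg[[s]], 0),
                    numeric(n)), Rd = -1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    theta_lin <- NULL
  } else {
    theta_lin <- qr.coef(qrX, A)
  }

  ok <- TRUE; converged <- TRUE
  if (gm_mode == "infinite") {
    if (is.null(theta_lin)) {
      return(fit_result_invalid(curve, assignment, ord, k, gm_mode,
                                reason = "rank-deficient design (parameters not identifiable)"))
    }
    theta <- theta_lin
    fitted_vals <- as.numeric(X %*% theta)
    gm_val <- GM_INFINITE
  } else {
    par_names <- c(present, "Rd", if (gm_mode == "fitted") "gm")
    obj <- function(th) {
      names(th) <- par_names
      gm_v <- if (gm_mode == "fitted") th[["gm"]] else gm
      if (gm_v <= 0) return(1e12)
      if (any(th[present] <= 0)) return(1e12)
      pred <- predict_assigned(ci, assignment, th, present, kt, jc, jg, gm_v)
      if (any(!is.finite(pred))) return(1e12)
      sum((A - pred)^2)
    }
    starts <- finite_gm_starts(theta_lin, present, gm_mode, A)
    if (gm_mode == "fitted") {
      starts <- unlist(lapply(exp(seq(log(0.5), log(50), length.out = 4)),
                              function(g) lapply(starts, function(s) c(s, gm = g))),
                       recursive = FALSE)
    }
    best <- NULL
    for (s0 in starts) {
      fit <- stats::optim(s0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    # polish from the best point
    best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-14))
    converged <- best$convergence == 0
    theta <- best$par
    names(theta) <- par_names
    gm_val <- if (gm_mode == "fitted") theta[["gm"]] else gm
    fitted_vals <- predict_assigned(ci, assignment, theta, present, kt, jc, jg, gm_val)
  }

  est <- as.list(theta)
  rates <- list(Vcmax = est$C, J = est$J, Tp = est$P, Rd = est$Rd)
  pos_ok <- all(vapply(c("Vcmax", "J", "Tp")[c("C", "J", "P") %in% present],
                       function(nm) isTRUE(rates[[nm]] > 0), logical(1)))
  ok <- ok && pos_ok && converged

  cost <- sum((A - fitted_vals)^2)
  if (!ok)
    return(fit_result_invalid(curve, assignment, ord, k, gm_mode,
                              reason = "non-positive rate or non-convergence",
                              cost = cost))

  # parameters at mean leaf temperature; fill absent states with stand-ins
  # large enough never to limit, so forward evaluation stays defined.
  Vc <- if (!is.null(rates$Vcmax)) rates$Vcmax else NA_real_
  Jr <- if (!is.null(rates$J)) rates$J else NA_real_
  Tp <- if (!is.null(rates$Tp)) rates$Tp else NA_real_
  Rd <- rates$Rd
  params <- fvcb_params(Vcmax = if (is.na(Vc)) 1e6 else Vc,
                        J = if (is.na(Jr)) 1e7 else Jr,
                        Tp = Tp, Rd = Rd,
                        gm_mode = if (gm_mode == "infinite") "infinite" else "fixed",
                        gm = gm_val, T_ref = Tm, j_stoich = j_stoich)
  params_25 <- list(
    Vcmax25 = if (is.na(Vc)) NA_real_ else normalize_to_25(Vc, k$Ea_Vcmax, Tm),
    J25 = if (is.na(Jr)) NA_real_ else normalize_to_25(Jr, k$Ea_J, Tm),
    Rd25 = normalize_to_25(Rd, k$Ea_Rd, Tm),
    Tp = Tp)
  trans <- list(
    ci_cJ = if (all(c("C", "J") %in% present)) transition_ci_cJ(params, k, Tm) else NA_real_,
    ci_JP = if (all(c("J", "P") %in% present)) transition_ci_JP(params, k, Tm) else NA_real_)

  structure(list(params = params, params_25 = params_25,
                 estimates = list(Vcmax = Vc, J = Jr, Tp = Tp, Rd = Rd),
                 assignment = assignment, order = ord, cost = cost, ok = TRUE,
                 rd_positive = Rd > 0, admissible = NA, violators = integer(0),
                 transitions = trans, fitted = fitted_vals,
                 n_states = length(present), present = present,
                 n_swing_reassignments = 0L,
                 constants_label = k$source_label, gm_mode = gm_mode,
                 T_leaf = Tm),
            class = "aci_fit")
}

fit_result_invalid <- function(curve, assignment, ord, k, gm_mode, reason,
                               cost = Inf) {
  structure(list(params = NULL, params_25 = NULL, estimates = NULL,
                 assignment = assignment, order = ord, cost = cost, ok = FALSE,
                 rd_positive = NA, admissible = FALSE, violators = integer(0),
                 transitions = list(ci_cJ = NA_real_, ci_JP = NA_real_),
                 fitted = NULL, n_states = length(unique(assignment)),
                 present = unique(assignment), n_swing_reassignments = 0L,
                 constants_label = k$source_label, gm_mode = gm_mode,
                 reason = reason, T_leaf = mean_t_leaf(curve)),
            class = "aci_fit")
}

predict_assigned <- function(ci, assignment, theta, present, kt, jc, jg, gm) {
  theta <- as.list(theta)
  out <- numeric(length(ci))
  for (s in present) {
    i <- assignment == s
    out[i] <- switch(s,
      C = branch_quadratic(ci[i], theta$C, kt$Km, kt$GammaStar, theta$Rd, gm),
      J = branch_quadratic(ci[i], theta$J / jc, jg * kt$GammaStar / jc,
                           kt$GammaStar, theta$Rd, gm),
      P = 3 * theta$P - theta$Rd)
  }
  out
}

# Deterministic starts for the finite-gm search: the infinite-gm linear
# solution plus a coarse grid over the physiological parameter ranges.
finite_gm_starts <- function(theta_lin, present, gm_mode, A) {
  grid_one <- function(vc, j, tp, rd) {
    s <- c(C = vc, J = j, P = tp)[present]
    c(s, Rd = rd)
  }
  starts <- list()
  if (!is.null(theta_lin)) starts[[1]] <- theta_lin[!is.na(theta_lin)]
  amax <- max(A)
  starts <- c(starts, list(
    grid_one(60, 120, 8, 0.5), grid_one(150, 250, 15, 1),
    grid_one(300, 450, 30, 2),
    grid_one(max(4 * amax, 40), max(6 * amax, 60), max(amax / 2.5, 4), 0.5)))
  starts
}

#' @export
print.aci_fit <- function(x, ...) {
  if (!x$ok) {
    cat("Invalid A/ci fit (", x$reason, "); cost =", x$cost, "\n")
    return(invisible(x))
  }
  e <- x$estimates
  cat(sprintf("A/ci fit [%s, gm_mode=%s]: states %s, cost %.5g\n",
              x$constants_label, x$gm_mode, paste(x$present, collapse = ""),
              x$cost))
  cat(sprintf("  Vcmax=%.2f J=%.2f Tp=%s Rd=%.3f (at %.1f degC)\n",
              e$Vcmax, e$J, if (is.na(e$Tp)) "absent" else sprintf("%.2f", e$Tp),
              e$Rd, x$T_leaf))
  cat(sprintf("  at 25 degC: Vcmax25=%.2f J25=%.2f\n",
              x$params_25$Vcmax25, x$params_25$J25))
  cat(sprintf("  transitions: ci_cJ=%s ci_JP=%s Pa; admissible=%s\n",
              fmtNA(x$transitions$ci_cJ), fmtNA(x$transitions$ci_JP),
              x$admissible))
  invisible(x)
}

fmtNA <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)

#' Check admissibility of a fitted assignment
#'
#' A fit is admissible iff, for every observation, the assigned limitation
#' state is the minimizing branch of the fitted model at that observation's
#' ci (tolerance 1e-6 µmol m-2 s-1); equivalently, the fitted transitions
#' bracket the assigned segments. Only branches whose parameter was fitted
#' participate.
#'
#' @param fit an `aci_fit`.
#' @param curve the [aci_curve()] it was fitted to.
#' @param k kinetic constants used for the fit.
#' @param tol rate tolerance (µmol m-2 s-1).
#' @return The fit with `admissible` and `violators` (sorted-order indices)
#'   filled in.
#' @export
check_admissibility <- function(fit, curve, k = wheat_constants(), tol = 1e-6) {
  k <- resolve_constants(k)
  if (!fit$ok) { fit$admissible <- FALSE; return(fit) }
  ci <- curve$ci[fit$order]
  rates <- branch_rate_matrix(ci, fit, k)
  assigned <- rates[cbind(seq_along(ci), match(fit$assignment, colnames(rates)))]
  viol <- which(assigned > apply(rates, 1, min) + tol)
  fit$admissible <- length(viol) == 0
  fit$violators <- viol
  fit
}

# Branch rates of the fitted model at each ci, one column per present state.
branch_rate_matrix <- function(ci, fit, k) {
  kt <- kinetics_at(k, fit$T_leaf)
  p <- fit$params; e <- fit$estimates
  cols <- fit$present
  m <- matrix(NA_real_, length(ci), length(cols), dimnames = list(NULL, cols))
  for (s in cols) {
    m[, s] <- switch(s,
      C = branch_quadratic(ci, e$Vcmax, kt$Km, kt$GammaStar, e$Rd, p$gm),
      J = branch_quadratic(ci, e$J / p$jc, p$jg * kt$GammaStar / p$jc,
                           kt$GammaStar, e$Rd, p$gm),
      P = 3 * e$Tp - e$Rd)
  }
  m
}

#' Resolve co-limited "swinging points"
#'
#' Boundary observations where the two adjoining fitted branch rates differ
#' by less than `tol_colimit` are co-limited: their state assignment is
#' ambiguous. Each such observation is reassigned to the adjacent state and
#' the curve refitted; the lowest-cost admissible result is returned (a
#' no-op when no co-limited boundary points exist). The count of tested
#' reassignments is recorded in `n_swing_reassignments`.
#'
#' @param best an admissible `aci_fit`.
#' @inheritParams check_admissibility
#' @param tol_colimit co-limitation tolerance (µmol m-2 s-1).
#' @param min_per_state minimum observations per present state.
#' @return An `aci_fit` with cost less than or equal to the input's.
#' @export
resolve_swinging_points <- function(best, curve, k = wheat_constants(),
                                    tol_colimit = 0.5, min_per_state = 2) {
  k <- resolve_constants(k)
  if (!best$ok) return(best)
  ci <- curve$ci[best$order]
  asg <- best$assignment
  rates <- branch_rate_matrix(ci, best, k)
  n <- length(asg)
  cand <- list()
  bounds <- which(asg[-1] != asg[-n])  # i: boundary between i and i+1
  for (b in bounds) {
    s_left <- asg[b]; s_right <- asg[b + 1]
    for (i in c(b, b + 1)) {
      gap <- abs(rates[i, s_left] - rates[i, s_right])
      if (is.na(gap) || gap >= tol_colimit) next
      alt <- asg
      alt[i] <- if (i == b) s_right else s_left
      if (!valid_assignment(alt, min_per_state)) next
      cand[[length(cand) + 1L]] <- alt
    }
  }
  n_tested <- 0L
  out <- best
  for (alt in cand) {
    f <- try(fit_assignment(curve, alt, k, gm_mode = best$gm_mode,
                            gm = if (!is.null(best$params)) best$params$gm else 5.5),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    n_tested <- n_tested + 1L
    f <- check_admissibility(f, curve, k)
    if (f$ok && f$admissible && f$cost < out$cost) out <- f
  }
  out$n_swing_reassignments <- n_tested
  out
}

valid_assignment <- function(asg, min_per_state) {
  r <- rle(asg)
  ordered <- identical(r$values, c("C", "J", "P")[c("C", "J", "P") %in% r$values])
  ordered && all(r$lengths >= min_per_state)
}

#' Fit an A/ci curve by exhaustive limitation-state enumeration
#'
#' The full fitting procedure: observations are sorted by ci, every ordered
#' contiguous limitation-state assignment (see [enumerate_assignments()])
#' is fitted by least squares, inadmissible fits are discarded, and the
#' lowest-cost admissible fit is refined by swinging-point resolution.
#' Single-state assignments additionally require n >= 3 observations
#' (parameters + 1). Ties within 1e-8 in cost are broken by fewer
#' limitation states, then by positive day respiration, then by enumeration
#' order. Fitted rates are reported both at the curve's mean leaf
#' temperature and normalized to 25 degC.
#'
#' Panel mode — the reduced parameterization used for large screens where
#' not every line expresses a TPU limitation — is obtained with
#' `states = c("C", "J")`.
#'
#' @inheritParams fit_assignment
#' @param states limitation states allowed, subset of c("C","J","P").
#' @param min_per_state minimum observations per present state.
#' @param tol_colimit swinging-point co-limitation tolerance
#'   (µmol m-2 s-1).
#' @param resolve_swing logical; run swinging-point resolution on the best
#'   fit.
#' @return The accepted `aci_fit`. If no assignment is admissible, an
#'   object of class `aci_fit_failure` listing per-assignment costs.
#' @export
fit_aci <- function(curve, k = wheat_constants(),
                    gm_mode = c("infinite", "fixed", "fitted"), gm = 5.5,
                    states = c("C", "J", "P"), min_per_state = 2,
                    tol_colimit = 0.5, resolve_swing = TRUE,
                    j_stoich = "nadph") {
  gm_mode <- match.arg(gm_mode)
  k <- resolve_constants(k)
  n <- nrow(curve)
  if (n < 4) stop("need >= 4 observations to fit an A/ci curve")
  assignments <- enumerate_assignments(n, states, min_per_state)
  fits <- vector("list", length(assignments))
  for (i in seq_along(assignments)) {
    f <- try(fit_assignment(curve, assignments[[i]], k, gm_mode = gm_mode,
                            gm = gm, j_stoich = j_stoich), silent = TRUE)
    if (inherits(f, "try-error")) next
    fits[[i]] <- check_admissibility(f, curve, k)
  }
  keep <- which(vapply(fits, function(f)
    !is.null(f) && f$ok && isTRUE(f$admissible), logical(1)))
  if (length(keep) == 0) {
    costs <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$cost,
                    numeric(1))
    return(structure(list(costs = costs, assignments = assignments,
                          message = "no admissible limitation-state assignment"),
                     class = "aci_fit_failure"))
  }
  cost <- vapply(fits[keep], `[[`, numeric(1), "cost")
  nstates <- vapply(fits[keep], `[[`, numeric(1), "n_states")
  rdpos <- vapply(fits[keep], `[[`, logical(1), "rd_positive")
  best_cost <- min(cost)
  tied <- which(cost <= best_cost + 1e-8)
  tied <- tied[order(nstates[tied], !rdpos[tied], tied)]
  best <- fits[[keep[tied[1]]]]
  if (resolve_swing)
    best <- resolve_swinging_points(best, curve, k, tol_colimit, min_per_state)
  best
}

#' PSII quantum-yield consistency diagnostic
#'
#' Chlorophyll-fluorescence Phi_PSII rises with ci while assimilation is
#' Rubisco-limited (electron demand grows) and plateaus once electron
#' transport limits. This diagnostic estimates the ci at which Phi_PSII
#' stops increasing (first 3-point window whose slope falls below
#' `slope_threshold`) and reports its distance from the fitted Rubisco-to-
#' RuBP transition ci_cJ. Purely diagnostic; never alters the fit.
#'
#' @param fit an `aci_fit`.
#' @param curve the fitted [aci_curve()]; needs `phi_psii` on >= 6
#'   observations.
#' @param slope_threshold plateau slope threshold (Phi_PSII per Pa).
#' @return list with `available`, `ci_plateau` (Pa or NA), `ci_cJ`,
#'   `delta_pa` (|ci_plateau - ci_cJ|), `message`.
#' @export
phi_psii_diagnostic <- function(fit, curve, slope_threshold = 0.002) {
  ord <- order(curve$ci)
  ci <- curve$ci[ord]; phi <- curve$phi_psii[ord]
  use <- is.finite(ci) & is.finite(phi)
  if (sum(use) < 6)
    return(list(available = FALSE, ci_plateau = NA_real_, ci_cJ = NA_real_,
                delta_pa = NA_real_, message = "insufficient Phi_PSII data"))
  ci <- ci[use]; phi <- phi[use]
  m <- length(ci)
  slopes <- vapply(seq_len(m - 2), function(i) {
    w <- i:(i + 2)
    stats::coef(stats::lm(phi[w] ~ ci[w]))[2]
  }, numeric(1))
  if (all(abs(slopes) < slope_threshold))
    return(list(available = TRUE, ci_plateau = NA_real_,
                ci_cJ = fit$transitions$ci_cJ, delta_pa = NA_real_,
                message = "plateau onset undefined (Phi_PSII constant)"))
  rising <- slopes >= slope_threshold
  if (all(rising))
    return(list(available = TRUE, ci_plateau = NA_real_,
                ci_cJ = fit$transitions$ci_cJ, delta_pa = NA_real_,
                message = "no J-limitation signature (Phi_PSII rising throughout)"))
  first_rise <- which(rising)[1]
  flat_after <- which(!rising & seq_along(slopes) > first_rise)
  if (length(flat_after) == 0)
    return(list(available = TRUE, ci_plateau = NA_real_,
                ci_cJ = fit$transitions$ci_cJ, delta_pa = NA_real_,
                message = "no J-limitation signature (Phi_PSII rising throughout)"))
  ci_plateau <- ci[flat_after[1] + 1]  # centre of the first flat window
  ci_cJ <- fit$transitions$ci_cJ
  list(available = TRUE, ci_plateau = ci_plateau, ci_cJ = ci_cJ,
       delta_pa = if (is.na(ci_cJ)) NA_real_ else abs(ci_plateau - ci_cJ),
       message = "ok")
}
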