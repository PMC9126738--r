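test_that("assignment enumeration matches brute-force counting", {
  expect_length(enumerate_assignments(6, c("C", "J", "P"), 2), 13)
  expect_length(enumerate_assignments(2, "C", 2), 1)
  expect_length(enumerate_assignments(3, c("C", "J"), 2), 2)  # no 2+2 split fits
  for (case in list(list(n = 5, s = c("C", "J", "P"), m = 2),
                    list(n = 7, s = c("C", "J"), m = 2),
                    list(n = 8, s = c("C", "J", "P"), m = 3))) {
    got <- enumerate_assignments(case$n, case$s, case$m)
    oracle <- brute_assignments(case$n, case$s, case$m)
    expect_length(got, nrow(oracle))
    # every enumerated assignment is contiguous, ordered and unique
    keys <- vapply(got, paste, character(1), collapse = "")
    expect_equal(anyDuplicated(keys), 0L)
  }
  expect_error(enumerate_assignments(5, character(0)), "empty state set")
})

test_that("single-assignment fits are exact least squares (nls oracle) and handle duplicates", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 120, J = 5000, Rd = 1.2, seed = 4)  # Rubisco-limited throughout
  asg <- rep("C", nrow(cv))
  f <- fit_assignment(cv, asg, k)
  kt <- kinetics_at(k, 25)
  gam <- kt$GammaStar; km <- kt$Km
  d <- data.frame(ci = sort(cv$ci), A = cv$A[order(cv$ci)])
  o <- nls(A ~ V * (ci - gam) / (ci + km) - R, data = d,
           start = list(V = 80, R = 0.5))
  expect_equal(f$estimates$Vcmax, coef(o)[["V"]], tolerance = 1e-6)
  expect_equal(f$estimates$Rd, coef(o)[["R"]], tolerance = 1e-6)
  # duplicated observations leave the estimates unchanged, double the cost
  cv2 <- aci_curve(rbind(as.data.frame(cv), as.data.frame(cv)))
  f2 <- fit_assignment(cv2, rep("C", nrow(cv2)), k)
  expect_equal(f2$estimates$Vcmax, f$estimates$Vcmax, tolerance = 1e-8)
  expect_equal(f2$cost, 2 * f$cost, tolerance = 1e-6)
})

test_that("noiseless TPU-expressing curve is recovered with a C/J/P assignment", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 139, J = 247, Tp = 17.0, Rd = 0.46, seed = 1)
  f <- fit_aci(cv, k)
  expect_true(f$ok && f$admissible)
  expect_setequal(f$present, c("C", "J", "P"))
  expect_equal(f$estimates$Vcmax, 139, tolerance = 1e-3)
  expect_equal(f$estimates$J, 247, tolerance = 1e-3)
  expect_equal(f$estimates$Tp, 17.0, tolerance = 1e-3)
  expect_equal(f$estimates$Rd, 0.46, tolerance = 1e-2)
  tr <- attr(cv, "true_transitions")
  expect_equal(f$transitions$ci_cJ, tr$ci_cJ, tolerance = 1e-4)
  expect_equal(f$transitions$ci_JP, tr$ci_JP, tolerance = 1e-4)
})

test_that("curve without TPU limitation selects no P state", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 136, J = 255, Rd = 0.42, seed = 2)
  f <- fit_aci(cv, k)
  expect_true(f$ok && f$admissible)
  expect_false("P" %in% f$present)
  expect_equal(f$estimates$Vcmax, 136, tolerance = 1e-3)
  expect_equal(f$estimates$J, 255, tolerance = 1e-3)
})

test_that("panel mode restricts the engine to C and J states", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 139, J = 247, Tp = 17.0, Rd = 0.46,
                   protocol = "li6400", seed = 3)
  f <- fit_aci(cv, k, states = c("C", "J"))
  expect_true(all(f$present %in% c("C", "J")))
  expect_true(f$ok && f$admissible)
})

test_that("admissibility equals the brute-force pointwise argmin scan", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 120, J = 210, Rd = 0.8, seed = 6)
  n <- nrow(cv)
  for (split in c(3, 8, 12)) {
    asg <- c(rep("C", split), rep("J", n - split))
    f <- fit_assignment(cv, asg, k)
    f <- check_admissibility(f, cv, k)
    expect_equal(f$admissible, brute_admissible(f, cv, k))
  }
})

test_that("a fit whose transition lands inside its own C segment is inadmissible", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 120, J = 210, Rd = 0.8, seed = 7)
  n <- nrow(cv)
  # force far too many points into the C segment: the fitted ci_cJ must
  # then fall inside it, violating state consistency
  asg <- c(rep("C", n - 2), rep("J", 2))
  f <- check_admissibility(fit_assignment(cv, asg, k), cv, k)
  expect_false(f$admissible)
  expect_gt(length(f$violators), 0)
  # all-C fit on an everywhere-Rubisco-limited curve is admissible
  cvc <- make_curve(Vcmax = 120, J = 5000, Rd = 1, seed = 8)
  fc <- check_admissibility(fit_assignment(cvc, rep("C", nrow(cvc)), k), cvc, k)
  expect_true(fc$admissible)
})

test_that("swinging-point resolution is a no-op without co-limited points and never raises cost", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 139, J = 247, Tp = 17, Rd = 0.46, seed = 1)
  best <- fit_aci(cv, k, resolve_swing = FALSE)
  res <- resolve_swinging_points(best, cv, k, tol_colimit = 0.5)
  expect_lte(res$cost, best$cost + 1e-12)
  # with a huge tolerance every boundary point is "co-limited": the result
  # must still never be worse
  res2 <- resolve_swinging_points(best, cv, k, tol_colimit = 50)
  expect_lte(res2$cost, best$cost + 1e-12)
  expect_gt(res2$n_swing_reassignments, 0)
  # a noisy point near the transition: both assignments tested, best kept
  cvn <- make_curve(Vcmax = 139, J = 247, Tp = 17, Rd = 0.46, noise_sd = 0.4,
                    seed = 11)
  fn <- fit_aci(cvn, k)
  expect_true(fn$ok && fn$admissible)
})

test_that("fitting is deterministic and validates its inputs", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 130, J = 240, Rd = 0.5, noise_sd = 0.5, seed = 9)
  f1 <- fit_aci(cv, k)
  f2 <- fit_aci(cv, k)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  expect_error(fit_aci(aci_curve(data.frame(ci = c(5, 10, 20), A = c(1, 5, 9))), k),
               ">= 4 observations")
  # too few observations for the parameter count
  expect_error(fit_assignment(aci_curve(data.frame(ci = c(5, 10, 20, 30),
                                                   A = c(1, 5, 9, 12)))[1:2, ],
                              rep("C", 2), k), "observations")
})

test_that("gm-infinite fit of a finite-gm curve yields apparent Vcmax below truth", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 150, J = 260, Rd = 1, gm_mode = "fixed", gm = 5.5,
                   seed = 10)
  f <- fit_aci(cv, k, gm_mode = "infinite")
  expect_true(f$ok)
  expect_lte(f$estimates$Vcmax, 150)
})

test_that("fixed-gm fitting recovers the generating parameters", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 150, J = 260, Rd = 1, gm_mode = "fixed", gm = 5.5,
                   seed = 3)
  f <- fit_aci(cv, k, gm_mode = "fixed", gm = 5.5)
  expect_true(f$ok && f$admissible)
  expect_equal(f$estimates$Vcmax, 150, tolerance = 5e-3)
  expect_equal(f$estimates$J, 260, tolerance = 5e-3)
})

test_that("PSII diagnostic locates the plateau near the fitted transition and flags degenerate input", {
  k <- wheat_constants()
  cv <- make_curve(Vcmax = 139, J = 247, Tp = 17, Rd = 0.46, seed = 1)
  f <- fit_aci(cv, k)
  d <- phi_psii_diagnostic(f, cv)
  expect_true(d$available)
  expect_lt(d$delta_pa, 8)  # within one CO2 step of the protocol
  cv_const <- cv; cv_const$phi_psii <- rep(0.5, nrow(cv))
  expect_match(phi_psii_diagnostic(f, cv_const)$message, "plateau onset undefined")
  cv_rise <- cv; cv_rise$phi_psii <- seq(0.2, 0.8, length.out = nrow(cv))[rank(cv$ci)]
  expect_match(phi_psii_diagnostic(f, cv_rise)$message, "no J-limitation")
  cv_few <- cv; cv_few$phi_psii[-(1:3)] <- NA
  expect_false(phi_psii_diagnostic(f, cv_few)$available)
})
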