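# Shared fixtures for the test suite.

# Constant set engineered for hand arithmetic: GammaStar = 4 Pa and
# Km = Kc (1 + O/Ko) = 35 * (1 + 21/21) = 70 Pa at 25 degC.
hand_constants <- function() {
  kinetic_constants(Kc25 = 35, Ko25 = 21, GammaStar25 = 4, O = 21,
                    Ea_Kc = 60000, Ea_Ko = 36000, Ea_GammaStar = 30000,
                    Ea_Vcmax = 65000, Ea_J = 43000, Ea_Rd = 46000,
                    source_label = "hand")
}

# Noiseless synthetic curve from known truth on the 16-point protocol.
make_curve <- function(Vcmax = 139, J = 247, Tp = NA_real_, Rd = 0.46,
                       noise_sd = 0, seed = 1, protocol = "li6800",
                       gm_mode = "infinite", gm = 5.5,
                       k = wheat_constants(), genotype = NA_character_) {
  p <- fvcb_params(Vcmax = Vcmax, J = J, Tp = Tp, Rd = Rd,
                   gm_mode = gm_mode, gm = gm)
  generate_aci_curve(p, k, curve_protocol(protocol, noise_sd = noise_sd),
                     seed = seed, genotype = genotype)
}

# Independent brute-force enumeration of contiguous ordered assignments,
# used as the oracle for enumerate_assignments.
brute_assignments <- function(n, states, min_per_state) {
  all_states <- c("C", "J", "P")
  grids <- rep(list(all_states[all_states %in% states]), n)
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  keep <- apply(combos, 1, function(asg) {
    r <- rle(as.character(asg))
    ord <- c("C", "J", "P")[c("C", "J", "P") %in% r$values]
    identical(r$values, ord) && all(r$lengths >= min_per_state)
  })
  combos[keep, , drop = FALSE]
}

# Pointwise argmin admissibility oracle: the assigned branch must be a
# minimizing branch of the fitted model at every observation.
brute_admissible <- function(fit, curve, k) {
  ci <- curve$ci[fit$order]
  kt <- kinetics_at(k, fit$T_leaf)
  e <- fit$estimates
  ok <- TRUE
  for (i in seq_along(ci)) {
    r <- c()
    if ("C" %in% fit$present)
      r["C"] <- e$Vcmax * (ci[i] - kt$GammaStar) / (ci[i] + kt$Km) - e$Rd
    if ("J" %in% fit$present)
      r["J"] <- e$J * (ci[i] - kt$GammaStar) / (4 * ci[i] + 8 * kt$GammaStar) - e$Rd
    if ("P" %in% fit$present)
      r["P"] <- 3 * e$Tp - e$Rd
    if (r[fit$assignment[i]] > min(r) + 1e-6) ok <- FALSE
  }
  ok
}
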