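#' CO2-step measurement protocols
#'
#' The two stepped reference-CO2 protocols emulated by the curve
#' generator. "li6800" holds the leaf at 43 Pa, steps down through 35, 27,
#' 20, 15 and 5 Pa, then up through 43, 48, 53, 58, 63, 68, 73, 79, 85 and
#' 95 Pa (16 logged points, PAR 1500, 25 degC). "li6400" holds at 40 Pa,
#' steps down through 30, 20, 10 and 7 Pa, then up through 40, 45, 55, 70,
#' 100 and 120 Pa (11 points).
#'
#' @param name "li6800" or "li6400".
#' @param noise_sd additive observation noise on A (µmol m-2 s-1).
#' @param Q PAR (µmol m-2 s-1).
#' @param T_leaf leaf temperature (degC).
#' @return list of class `curve_protocol` with `name`, `ca_steps` (Pa),
#'   `Q`, `T_leaf`, `noise_sd`.
#' @export
curve_protocol <- function(name = c("li6800", "li6400"), noise_sd = 0,
                           Q = 1500, T_leaf = 25) {
  name <- match.arg(name)
  ca_steps <- switch(name,
    li6800 = c(43, 35, 27, 20, 15, 5, 43, 48, 53, 58, 63, 68, 73, 79, 85, 95),
    li6400 = c(40, 30, 20, 10, 7, 40, 45, 55, 70, 100, 120))
  structure(list(name = name, ca_steps = ca_steps, Q = Q, T_leaf = T_leaf,
                 noise_sd = noise_sd), class = "curve_protocol")
}

#' Stomatal-conductance model for synthetic curves
#'
#' A logistic decline of g_s with the sample-cell CO2 pressure between two
#' end-points, emulating the falling stomatal response along the CO2 ramp.
#' Synthetic-only plumbing: real data carry their measured g_s.
#'
#' @param gs_max,gs_min end-point conductances (mol m-2 s-1).
#' @param ca_mid midpoint (Pa) and `scale` width (Pa) of the decline.
#' @return function of ca returning g_s.
#' @export
gs_logistic <- function(gs_max = 0.46, gs_min = 0.26, ca_mid = 60, scale = 20) {
  function(ca) gs_min + (gs_max - gs_min) / (1 + exp((ca - ca_mid) / scale))
}

ATM_PRESSURE_KPA <- 101.325

# Total CO2 conductance in µmol m-2 s-1 Pa-1 from stomatal gs (mol m-2 s-1,
# water basis): divide by 1.6 for CO2 diffusivity, convert mole-fraction
# basis to partial-pressure basis at atmospheric pressure.
gs_to_gc_pa <- function(gs, pressure_kpa = ATM_PRESSURE_KPA) {
  gs / 1.6 / (pressure_kpa * 1000) * 1e6
}

#' Generate a synthetic A/ci curve from known FvCB parameters
#'
#' For each reference-CO2 step the intercellular CO2 is solved
#' self-consistently from the supply function A = g_c (ca - ci) with the
#' stomatal model's g_s, the noiseless assimilation is evaluated with the
#' forward FvCB model, Gaussian noise of sd `protocol$noise_sd` is added,
#' and Phi_PSII is emitted proportional to the electron transport actually
#' used (rising while Rubisco-limited, saturating at J). The true
#' parameters and transitions are recorded in attributes for round-trip
#' tests.
#'
#' @param true_params an [fvcb_params()] object (the generating truth).
#' @param k kinetic constants.
#' @param protocol a [curve_protocol()].
#' @param gs_model function of ca giving g_s (mol m-2 s-1); default
#'   [gs_logistic()].
#' @param seed integer seed (noise reproducibility); NULL leaves the RNG
#'   state alone.
#' @param leaf_id,genotype labels.
#' @return An [aci_curve()] with attributes `true_params`,
#'   `true_transitions`.
#' @export
generate_aci_curve <- function(true_params, k = wheat_constants(),
                               protocol = curve_protocol(), gs_model = gs_logistic(),
                               seed = NULL, leaf_id = "synthetic",
                               genotype = NA_character_) {
  k <- resolve_constants(k)
  if (!is.null(seed)) set.seed(seed)
  ca <- protocol$ca_steps
  Tm <- protocol$T_leaf
  kt <- kinetics_at(k, Tm)
  gs <- gs_model(ca)
  gc <- gs_to_gc_pa(gs)
  n <- length(ca)
  ci <- numeric(n); A_true <- numeric(n)
  for (i in seq_len(n)) {
    f <- function(x) gc[i] * (ca[i] - x) -
      net_assimilation(x, true_params, k, T_leaf = Tm)$A
    ci[i] <- stats::uniroot(f, c(0, max(300, 3 * ca[i])), tol = 1e-10)$root
    A_true[i] <- net_assimilation(ci[i], true_params, k, T_leaf = Tm)$A
  }
  if (all(A_true < -true_params$Rd + 1e-12))
    stop("degenerate parameters: assimilation below -Rd everywhere")
  A <- A_true + stats::rnorm(n, 0, protocol$noise_sd)
  # electron transport actually used, capped at J; saturates once J-limited
  ju <- ifelse(ci > kt$GammaStar + 1e-9,
               pmin(true_params$J,
                    (A_true + true_params$Rd) *
                      (true_params$jc * ci + true_params$jg * kt$GammaStar) /
                      (ci - kt$GammaStar)),
               true_params$J * 0.2)
  phi <- pmin(1, ju / (0.425 * protocol$Q))
  curve <- aci_curve(data.frame(ci = ci, A = A, gs = gs, ca = ca,
                                T_leaf = Tm, Q = protocol$Q, phi_psii = phi,
                                sequence_index = seq_len(n)),
                     leaf_id = leaf_id, genotype = genotype,
                     environment = "synthetic")
  attr(curve, "true_params") <- true_params
  attr(curve, "true_transitions") <- list(
    ci_cJ = transition_ci_cJ(true_params, k, Tm),
    ci_JP = transition_ci_JP(true_params, k, Tm))
  attr(curve, "A_true") <- A_true
  curve
}

#' Generate a synthetic light-response table
#'
#' Non-rectangular hyperbola A(Q) used only to exercise the operating-rate
#' extraction: A = (phi Q + Amax - sqrt((phi Q + Amax)^2 - 4 theta phi Q
#' Amax)) / (2 theta) - Rd.
#'
#' @param Amax light-saturated gross assimilation (µmol m-2 s-1).
#' @param phi apparent quantum yield; `theta` curvature; `Rd` respiration.
#' @param Q_levels PAR levels (µmol m-2 s-1).
#' @return data.frame with `Q` and `A`.
#' @export
generate_light_response <- function(Amax = 28, phi = 0.06, theta = 0.7,
                                    Rd = 1,
                                    Q_levels = c(1800, 1500, 1000, 500, 250,
                                                 120, 50, 25)) {
  s <- phi * Q_levels + Amax
  A <- (s - sqrt(s^2 - 4 * theta * phi * Q_levels * Amax)) / (2 * theta) - Rd
  data.frame(Q = Q_levels, A = A)
}

#' Panel specification for the trait-table generator
#'
#' Defaults describe an 80-line panel plus one check cultivar, measured in
#' two environments (field, glasshouse) with 4 replicates each. Each trait
#' has environment means, a genotype-effect SD shared across environments
#' through a bivariate-normal genotype effect with cross-environment
#' correlation `rho`, and a replicate noise SD. Default `rho` is 0.6 for
#' agronomic traits (GY, TGW, HI, height, days to anthesis) and 0 for
#' photosynthetic traits, the qualitative pattern the generator is meant
#' to emulate.
#'
#' @param n_genotypes number of panel lines (default 80).
#' @param n_check number of check cultivars appended (default 1).
#' @param n_rep replicates per environment (default 4).
#' @param traits data.frame with columns `name`, `mean_field`, `mean_gh`,
#'   `gen_sd`, `rep_sd`, `rho`; default built in.
#' @param seed integer seed.
#' @return list of class `panel_spec`.
#' @export
panel_spec <- function(n_genotypes = 80, n_check = 1, n_rep = 4,
                       traits = NULL, seed = 1) {
  if (is.null(traits)) {
    traits <- data.frame(
      name = c("A_sat", "A_op", "Vcmax25", "J", "Narea", "LMA",
               "GY", "TGW", "HI", "height", "days_z65"),
      mean_field = c(23, 18, 150, 220, 2.5, 50, 520, 40, 0.44, 100, 90),
      mean_gh    = c(26, 16, 140, 250, 2.2, 46, 480, 38, 0.42, 95, 78),
      gen_sd     = c(2, 1.5, 15, 20, 0.2, 4, 40, 3, 0.02, 8, 5),
      rep_sd     = c(1.5, 1.2, 10, 12, 0.15, 3, 25, 1.5, 0.015, 4, 2),
      rho        = c(0, 0, 0, 0, 0, 0, 0.6, 0.6, 0.6, 0.6, 0.6),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(abs(traits$rho) <= 1), all(traits$gen_sd >= 0),
            all(traits$rep_sd >= 0))
  structure(list(n_genotypes = n_genotypes, n_check = n_check, n_rep = n_rep,
                 traits = traits, seed = seed), class = "panel_spec")
}

#' Generate field and glasshouse panel trait tables
#'
#' Genotype effects are drawn once per trait from a bivariate normal with
#' the trait's cross-environment correlation `rho` and shared SD, then
#' replicate noise is added independently per environment. The derived
#' columns GM2 = (GY/TGW) x 1000 and biomass = GY/HI are computed from the
#' simulated GY, TGW and HI row-wise, so the yield-component identities
#' hold exactly by construction.
#'
#' @param spec a [panel_spec()].
#' @return list with `field` and `glasshouse` data.frames (genotype,
#'   environment, replicate, trait columns) and `genotype_effects` (the
#'   true per-trait effects, for recovery tests).
#' @export
generate_panel <- function(spec = panel_spec()) {
  set.seed(spec$seed)
  ng <- spec$n_genotypes + spec$n_check
  genotypes <- c(sprintf("L%02d", seq_len(spec$n_genotypes)),
                 if (spec$n_check > 0) sprintf("CHK%d", seq_len(spec$n_check)))
  effects <- list()
  env_tables <- list(field = NULL, glasshouse = NULL)
  base <- expand.grid(genotype = genotypes, replicate = seq_len(spec$n_rep),
                      stringsAsFactors = FALSE)
  tabs <- list(
    field = data.frame(genotype = base$genotype, environment = "field",
                       replicate = base$replicate, stringsAsFactors = FALSE),
    glasshouse = data.frame(genotype = base$genotype, environment = "glasshouse",
                            replicate = base$replicate, stringsAsFactors = FALSE))
  for (ti in seq_len(nrow(spec$traits))) {
    tr <- spec$traits[ti, ]
    Sigma <- tr$gen_sd^2 * matrix(c(1, tr$rho, tr$rho, 1), 2)
    if (min(eigen(Sigma, only.values = TRUE)$values) < -1e-8)
      stop("invalid correlation matrix for trait ", tr$name)
    eff <- MASS::mvrnorm(ng, mu = c(0, 0), Sigma = Sigma)
    effects[[tr$name]] <- data.frame(genotype = genotypes,
                                     field = eff[, 1], glasshouse = eff[, 2])
    for (env in c("field", "glasshouse")) {
      mu <- if (env == "field") tr$mean_field else tr$mean_gh
      e <- eff[match(tabs[[env]]$genotype, genotypes),
               if (env == "field") 1 else 2]
      tabs[[env]][[tr$name]] <- mu + e +
        stats::rnorm(nrow(tabs[[env]]), 0, tr$rep_sd)
    }
  }
  for (env in c("field", "glasshouse")) {
    t <- tabs[[env]]
    if (all(c("GY", "TGW", "HI") %in% names(t))) {
      t$TGW <- pmax(t$TGW, 1)
      t$HI <- pmin(pmax(t$HI, 0.05), 1)
      yc <- yield_components(t$GY, t$TGW, t$HI)
      t$GM2 <- yc$GM2
      t$biomass <- yc$biomass
    }
    tabs[[env]] <- t
  }
  list(field = tabs$field, glasshouse = tabs$glasshouse,
       genotype_effects = effects)
}

#' Generate a toy two-sample variant table
#'
#' Plants biallelic SNP sites along each chromosome at the given density
#' and assigns genotype calls for two near-inbred samples so that each
#' region's expected identity-by-state fraction equals its profile value:
#' with probability `p` the second sample copies the first sample's call,
#' otherwise it is forced to a different call.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param site_density sites per bp (e.g. 1e-4).
#' @param similarity_profile data.frame with `chrom`, `start`, `end`
#'   (0-based half-open, bp) and `ibs_prob` in [0, 1]; regions not covered
#'   default to `default_prob`.
#' @param seed integer seed.
#' @param samples two sample names.
#' @param het_rate probability a call is heterozygous (near-inbred lines:
#'   low; default 0.02).
#' @param default_prob IBS probability outside profiled regions.
#' @return A `variant_table` with the two samples; attribute `profile`
#'   keeps the generating profile.
#' @export
generate_variant_table <- function(chrom_lengths, site_density = 1e-4,
                                   similarity_profile = NULL, seed = 1,
                                   samples = c("LINE51", "LINE64"),
                                   het_rate = 0.02, default_prob = 0.9) {
  stopifnot(site_density > 0)
  if (!is.null(similarity_profile))
    stopifnot(all(similarity_profile$ibs_prob >= 0 &
                  similarity_profile$ibs_prob <= 1))
  set.seed(seed)
  rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    n <- max(1L, round(len * site_density))
    pos <- sort(sample.int(len, min(n, len)))
    p_ibs <- rep(default_prob, length(pos))
    if (!is.null(similarity_profile)) {
      prof <- similarity_profile[similarity_profile$chrom == ch, , drop = FALSE]
      for (ri in seq_len(nrow(prof))) {
        inside <- (pos - 1) >= prof$start[ri] & (pos - 1) < prof$end[ri]
        p_ibs[inside] <- prof$ibs_prob[ri]
      }
    }
    ga <- ifelse(stats::runif(length(pos)) < het_rate, 1,
                 sample(c(0, 2), length(pos), replace = TRUE))
    same <- stats::runif(length(pos)) < p_ibs
    gb <- ga
    alt_call <- vapply(ga, function(g) sample(setdiff(c(0, 1, 2), g), 1),
                       numeric(1))
    gb[!same] <- alt_call[!same]
    df <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
    df[[samples[1]]] <- ga
    df[[samples[2]]] <- gb
    rows[[ch]] <- df
  }
  sites <- do.call(rbind, rows)
  rownames(sites) <- NULL
  vt <- variant_table(sites, contig_lengths = unlist(chrom_lengths))
  attr(vt, "profile") <- similarity_profile
  vt
}

#' Write a variant table as a minimal VCF
#'
#' Standard VCFv4.2 text with contig header lines and GT-only genotype
#' columns (0/0, 0/1, 1/1, ./.).
#'
#' @param vt a `variant_table`.
#' @param path output path.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (ch in names(vt$contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch,
                       as.integer(vt$contig_lengths[[ch]])), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vt$samples), collapse = "\t"), con)
  code <- c("0/0", "0/1", "1/1")
  s <- vt$sites
  gt_cols <- lapply(vt$samples, function(sm) {
    g <- s[[sm]]
    ifelse(is.na(g), "./.", code[g + 1])
  })
  lines <- do.call(paste, c(list(s$chrom, s$pos, ".", "A", "C", ".", ".",
                                 ".", "GT"), gt_cols, list(sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}
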