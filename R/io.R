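#' Default IRGA-log column map
#'
#' Maps the package's observation fields to the column names of a typical
#' infrared gas-analyser log export.
#' @return named character vector.
#' @export
irga_column_map <- function() {
  c(ci = "Ci", A = "A", gs = "gsw", ca = "CO2_s", T_leaf = "Tleaf",
    Q = "Qin", phi_psii = "PhiPS2", leaf_id = "leaf_id",
    genotype = "genotype", environment = "environment")
}

#' Read gas-exchange curves from delimited text
#'
#' Reads an IRGA-style log with a configurable column map, converts CO2
#' columns from ppm to Pa when requested (partial pressure = mole fraction
#' x atmospheric pressure), groups rows by leaf id and returns one
#' [aci_curve()] per leaf. Rows whose mapped numeric columns fail to parse
#' are skipped with a message and counted.
#'
#' @param path delimited text file with a header row.
#' @param column_map named vector mapping fields to file columns; see
#'   [irga_column_map()].
#' @param co2_units "Pa" or "ppm" for the `ci`/`ca` columns.
#' @param pressure_kpa atmospheric pressure for ppm conversion (kPa).
#' @param sep field separator (default ",").
#' @return named list of `aci_curve` objects; attribute `n_skipped`.
#' @export
read_gas_exchange <- function(path, column_map = irga_column_map(),
                              co2_units = c("Pa", "ppm"),
                              pressure_kpa = 101.325, sep = ",") {
  co2_units <- match.arg(co2_units)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  required <- c("ci", "A")
  for (f in required)
    if (!column_map[[f]] %in% names(raw))
      stop("missing required column: ", column_map[[f]], " (field ", f, ")")
  num_fields <- c("ci", "A", "gs", "ca", "T_leaf", "Q", "phi_psii")
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in num_fields) {
    cn <- column_map[[f]]
    df[[f]] <- if (!is.null(cn) && !is.na(cn) && cn %in% names(raw))
      suppressWarnings(as.numeric(raw[[cn]])) else NA_real_
  }
  bad <- !is.finite(df$ci) | !is.finite(df$A)
  if (any(bad)) message(sum(bad), " row(s) failed numeric parse and were skipped")
  df <- df[!bad, , drop = FALSE]
  raw <- raw[!bad, , drop = FALSE]
  if (co2_units == "ppm") {
    conv <- pressure_kpa / 1000  # ppm (µmol/mol) -> Pa
    df$ci <- df$ci * conv
    df$ca <- df$ca * conv
  }
  id_col <- column_map[["leaf_id"]]
  leaf_id <- if (!is.null(id_col) && !is.na(id_col) && id_col %in% names(raw))
    as.character(raw[[id_col]]) else rep("leaf1", nrow(df))
  geno_col <- column_map[["genotype"]]
  geno <- if (!is.null(geno_col) && !is.na(geno_col) && geno_col %in% names(raw))
    as.character(raw[[geno_col]]) else rep(NA_character_, nrow(df))
  env_col <- column_map[["environment"]]
  env <- if (!is.null(env_col) && !is.na(env_col) && env_col %in% names(raw))
    as.character(raw[[env_col]]) else rep(NA_character_, nrow(df))
  curves <- lapply(split(seq_len(nrow(df)), leaf_id), function(i) {
    d <- df[i, , drop = FALSE]
    d$sequence_index <- seq_along(i)
    aci_curve(d, leaf_id = leaf_id[i[1]], genotype = geno[i[1]],
              environment = env[i[1]])
  })
  attr(curves, "n_skipped") <- sum(bad)
  curves
}

#' Write gas-exchange curves to delimited text
#'
#' Inverse of [read_gas_exchange()] with the default column map and Pa
#' units; all curves are concatenated with their leaf/genotype labels.
#'
#' @param curves list of `aci_curve` objects.
#' @param path output path.
#' @export
write_curves <- function(curves, path) {
  rows <- lapply(curves, function(cv) {
    data.frame(leaf_id = attr(cv, "leaf_id"),
               genotype = attr(cv, "genotype"),
               environment = attr(cv, "environment"),
               Ci = cv$ci, A = cv$A, gsw = cv$gs, CO2_s = cv$ca,
               Tleaf = cv$T_leaf, Qin = cv$Q, PhiPS2 = cv$phi_psii,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Fit all curves of a list and tabulate the results
#'
#' @param curves list of `aci_curve` objects.
#' @param ... passed to [fit_aci()].
#' @return data.frame with one row per successfully fitted curve: labels,
#'   estimates at leaf temperature and at 25 degC, transitions, cost,
#'   admissibility, derived ratios.
#' @export
fit_aci_curves <- function(curves, ...) {
  rows <- lapply(curves, function(cv) {
    f <- fit_aci(cv, ...)
    if (inherits(f, "aci_fit_failure") || !f$ok) return(NULL)
    op <- operating_point(cv)
    ls <- tryCatch(stomatal_limitation(f, op, wheat_constants()),
                   error = function(e) NA_real_)
    data.frame(leaf_id = attr(cv, "leaf_id"), genotype = attr(cv, "genotype"),
               Vcmax = f$estimates$Vcmax, J = f$estimates$J,
               Tp = f$estimates$Tp, Rd = f$estimates$Rd,
               Vcmax25 = f$params_25$Vcmax25, J25 = f$params_25$J25,
               jv_ratio = j_v_ratio(f),
               ci_cJ = f$transitions$ci_cJ, ci_JP = f$transitions$ci_JP,
               operating_ci = op$ci_op, Ls = ls,
               iWUE = if (is.finite(op$gs_op) && op$gs_op > 0)
                 iwue(op$A_op, op$gs_op) else NA_real_,
               states = paste(f$present, collapse = ""),
               cost = f$cost, admissible = f$admissible,
               constants = f$constants_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Two-line deep-phenotyping workflow
#'
#' Fits every curve, derives the leaf-level traits, applies Tukey-fence
#' outlier filtering per trait within each genotype, and runs the
#' Shapiro-Wilk / F-test / t-test cascade between the two genotypes. The
#' output is shaped like a two-line trait comparison table: per trait,
#' group means with SEM, n after filtering, and the t-test p-value.
#'
#' @param curves list of `aci_curve` objects carrying exactly two distinct
#'   genotype labels.
#' @param traits trait columns of the fitted table to compare.
#' @param ... passed to [fit_aci()].
#' @return list: `fits` (per-curve table), `report` (per-trait comparison
#'   data.frame), `genotypes`.
#' @export
run_two_line_workflow <- function(curves,
                                  traits = c("Vcmax25", "J25", "jv_ratio",
                                             "ci_cJ", "Tp", "Rd",
                                             "operating_ci", "Ls"),
                                  ...) {
  fits <- fit_aci_curves(curves, ...)
  gens <- sort(unique(fits$genotype))
  if (length(gens) != 2) stop("two-line workflow requires exactly 2 genotypes, got ",
                              length(gens))
  rows <- lapply(traits, function(tr) {
    if (!tr %in% names(fits)) return(NULL)
    a <- tukey_filter(fits[[tr]][fits$genotype == gens[1]])$retained
    b <- tukey_filter(fits[[tr]][fits$genotype == gens[2]])$retained
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(trait = tr, mean_a = mean(a), sem_a = NA, n_a = length(a),
                        mean_b = mean(b), sem_b = NA, n_b = length(b),
                        flavour = NA, t_p = NA, stringsAsFactors = FALSE))
    cmp <- compare_two_lines(a, b)
    data.frame(trait = tr, mean_a = cmp$mean_a, sem_a = cmp$sem_a, n_a = cmp$n_a,
               mean_b = cmp$mean_b, sem_b = cmp$sem_b, n_b = cmp$n_b,
               flavour = cmp$flavour, t_p = cmp$t_p, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, Filter(Negate(is.null), rows))
  names(report) <- sub("_a$", paste0("_", gens[1]), names(report))
  names(report) <- sub("_b$", paste0("_", gens[2]), names(report))
  list(fits = fits, report = report, genotypes = gens)
}

#' Panel field-vs-glasshouse workflow
#'
#' Computes covariate-adjusted genotype means per environment and trait,
#' then the within-environment and cross-environment Pearson correlation
#' matrices.
#'
#' @param field,glasshouse trait tables (data.frames with `genotype` and
#'   trait columns). `glasshouse = NULL` with `mode = "cross"` is an
#'   error.
#' @param traits trait columns to analyse; default all shared numeric
#'   columns.
#' @param covariates covariate columns passed to
#'   [adjusted_genotype_means()].
#' @param mode "within:field", "within:glasshouse" or "cross".
#' @return list: `means` (per environment), `correlations` (the requested
#'   matrix set), `note`.
#' @export
run_panel_workflow <- function(field, glasshouse = NULL, traits = NULL,
                               covariates = character(0),
                               mode = c("cross", "within:field",
                                        "within:glasshouse")) {
  mode <- match.arg(mode)
  if (mode != "within:field" && is.null(glasshouse))
    stop("glasshouse table required for mode ", mode)
  tables <- list(field = field, glasshouse = glasshouse)
  means <- list()
  for (env in names(tables)) {
    t <- tables[[env]]
    if (is.null(t)) next
    if (is.null(traits))
      traits <- setdiff(names(t)[vapply(t, is.numeric, logical(1))],
                        c("replicate"))
    m <- NULL
    for (tr in traits) {
      am <- adjusted_genotype_means(t, tr, covariates)
      col <- stats::setNames(data.frame(am$genotype, am$mean,
                                        stringsAsFactors = FALSE),
                             c("genotype", tr))
      m <- if (is.null(m)) col else merge(m, col, by = "genotype")
    }
    means[[env]] <- m
  }
  correlations <- switch(mode,
    "within:field" = correlation_matrix(means$field[-1]),
    "within:glasshouse" = correlation_matrix(means$glasshouse[-1]),
    cross = correlation_matrix(means$field, means$glasshouse))
  list(means = means, correlations = correlations,
       note = paste("Adjusted means use fixed-effect covariate adjustment;",
                    "random year/block effects are not modelled."))
}
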