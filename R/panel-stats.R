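#' Tukey-fence outlier filtering
#'
#' Excludes values below Q1 - 1.5 IQR or above Q3 + 1.5 IQR. Quartiles use
#' linear interpolation between order statistics (type 7, the convention
#' documented for this package; Tukey's hinges differ slightly). With
#' fewer than 4 non-missing values no filtering is attempted and all
#' values are retained with a warning flag.
#'
#' @param values numeric vector (NAs dropped).
#' @return list with `retained`, `excluded`, `fences` (lower, upper) and
#'   `warning` (TRUE when too few values to filter).
#' @export
tukey_filter <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 4)
    return(list(retained = x, excluded = numeric(0),
                fences = c(NA_real_, NA_real_), warning = TRUE))
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  out <- x < fences[1] | x > fences[2]
  list(retained = x[!out], excluded = x[out], fences = fences,
       warning = FALSE)
}

#' Two-line trait comparison cascade
#'
#' The comparison applied per trait between two genotypes: Shapiro-Wilk
#' normality test per group, F-test for variance homogeneity, then a
#' two-sided two-sample t-test - pooled-variance if the F-test p-value
#' exceeds `alpha_var`, Welch otherwise. Reports group means with standard
#' errors.
#'
#' @param a,b numeric vectors (already outlier-filtered), n >= 2 each.
#' @param alpha_var F-test significance threshold for choosing the pooled
#'   t-test (default 0.05).
#' @return list: `mean_a`, `sem_a`, `n_a`, `mean_b`, `sem_b`, `n_b`,
#'   `shapiro_p_a`, `shapiro_p_b`, `f_p`, `flavour` ("pooled"/"welch"),
#'   `t_p`, `t_stat`, `degenerate` (TRUE with `t_p = NA` when a group has
#'   zero variance).
#' @export
compare_two_lines <- function(a, b, alpha_var = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  res <- list(mean_a = mean(a), sem_a = sem(a), n_a = length(a),
              mean_b = mean(b), sem_b = sem(b), n_b = length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    res$shapiro_p_a <- NA_real_; res$shapiro_p_b <- NA_real_
    res$f_p <- NA_real_; res$flavour <- NA_character_
    res$t_p <- NA_real_; res$t_stat <- NA_real_; res$degenerate <- TRUE
    return(res)
  }
  res$shapiro_p_a <- if (length(a) >= 3) stats::shapiro.test(a)$p.value else NA_real_
  res$shapiro_p_b <- if (length(b) >= 3) stats::shapiro.test(b)$p.value else NA_real_
  res$f_p <- stats::var.test(a, b)$p.value
  res$flavour <- if (res$f_p > alpha_var) "pooled" else "welch"
  tt <- stats::t.test(a, b, var.equal = res$flavour == "pooled")
  res$t_p <- tt$p.value
  res$t_stat <- unname(tt$statistic)
  res$degenerate <- FALSE
  res
}

#' Covariate-adjusted genotype means
#'
#' Per-environment fixed-effect linear model trait ~ genotype +
#' covariate(s); each covariate is retained only when its coefficient is
#' significant (p < `alpha`), otherwise the model is refitted without it.
#' Genotype least-squares means (covariates held at their mean) are
#' returned. The full random-effects machinery of multi-year field trials
#' (years, blocks, replications as random terms) is deliberately not
#' reproduced; every output carries a note stating this fixed-effect
#' deviation.
#'
#' @param table trait table data.frame with columns `genotype` and the
#'   trait/covariates.
#' @param trait trait column name.
#' @param covariates character vector of covariate column names (possibly
#'   empty).
#' @param alpha covariate retention threshold.
#' @return data.frame with `genotype`, `mean`, `se`, plus attributes
#'   `covariates_used` and `note`.
#' @export
adjusted_genotype_means <- function(table, trait, covariates = character(0),
                                    alpha = 0.05) {
  stopifnot(trait %in% names(table), all(covariates %in% names(table)))
  df <- table[is.finite(table[[trait]]), , drop = FALSE]
  df$genotype <- factor(df$genotype)
  if (nlevels(df$genotype) == 1) {
    out <- data.frame(genotype = levels(df$genotype),
                      mean = mean(df[[trait]]),
                      se = stats::sd(df[[trait]]) / sqrt(nrow(df)))
    attr(out, "covariates_used") <- character(0)
    attr(out, "note") <- paste("Fixed-effect covariate adjustment only;",
                               "random year/block/replicate effects not modelled.")
    return(out)
  }
  kept <- character(0)
  for (cv in covariates) {
    fml <- stats::as.formula(paste(trait, "~ genotype +", cv))
    fit <- try(stats::lm(fml, data = df), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (any(is.na(stats::coef(fit))))
      stop(sprintf("rank-deficient model: collinear column '%s'", cv))
    ct <- summary(fit)$coefficients
    row <- grep(paste0("^", cv), rownames(ct))
    if (length(row) && any(ct[row, "Pr(>|t|)"] < alpha)) kept <- c(kept, cv)
  }
  rhs <- if (length(kept)) paste(c("genotype", kept), collapse = " + ") else "genotype"
  fit <- stats::lm(stats::as.formula(paste(trait, "~", rhs)), data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient model: collinear terms ", paste(bad, collapse = ", "))
  }
  em <- as.data.frame(emmeans::emmeans(fit, "genotype"))
  out <- data.frame(genotype = as.character(em$genotype),
                    mean = em$emmean, se = em$SE)
  attr(out, "covariates_used") <- kept
  attr(out, "note") <- paste("Fixed-effect covariate adjustment only;",
                             "random year/block/replicate effects not modelled.")
  out
}

#' Pearson correlation matrix with probabilities
#'
#' Pairwise-complete Pearson correlations between trait columns, with
#' two-sided p-values from the t distribution and the per-pair n. In
#' cross-environment mode, genotype means from two environments are paired
#' by genotype and every field trait is correlated with every glasshouse
#' trait (same trait and across traits).
#'
#' @param table data.frame of per-genotype means: one row per genotype,
#'   numeric trait columns (non-numeric columns are ignored).
#' @param table2 optional second data.frame (cross-environment mode); must
#'   share a `genotype` column with `table`.
#' @param holm apply Holm adjustment to the p-values (default FALSE,
#'   matching a raw-p presentation).
#' @return list of matrices `r`, `p`, `n`. Within one table the `r` matrix
#'   is symmetric with unit diagonal; pairs with n < 3 get `r = NA`.
#' @export
correlation_matrix <- function(table, table2 = NULL, holm = FALSE) {
  if (is.null(table2)) {
    num <- table[vapply(table, is.numeric, logical(1))]
    X <- as.matrix(num); Y <- X
  } else {
    stopifnot("genotype" %in% names(table), "genotype" %in% names(table2))
    common <- intersect(table$genotype, table2$genotype)
    t1 <- table[match(common, table$genotype), , drop = FALSE]
    t2 <- table2[match(common, table2$genotype), , drop = FALSE]
    X <- as.matrix(t1[vapply(t1, is.numeric, logical(1))])
    Y <- as.matrix(t2[vapply(t2, is.numeric, logical(1))])
  }
  r <- matrix(NA_real_, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  p <- r; nmat <- r
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y))) {
    ok <- is.finite(X[, i]) & is.finite(Y[, j])
    n <- sum(ok)
    nmat[i, j] <- n
    if (n < 3) next
    rij <- stats::cor(X[ok, i], Y[ok, j])
    r[i, j] <- rij
    if (abs(rij) >= 1) { p[i, j] <- 0; next }
    tstat <- rij * sqrt((n - 2) / (1 - rij^2))
    p[i, j] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  if (is.null(table2)) diag(r) <- 1
  if (holm) {
    off <- if (is.null(table2)) upper.tri(p) else !is.na(p)
    p[off] <- stats::p.adjust(p[off], method = "holm")
    if (is.null(table2)) p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  list(r = r, p = p, n = nmat)
}

#' Long-format view of a correlation matrix
#' @param cm result of [correlation_matrix()].
#' @return data.frame with columns trait1, trait2, r, p, n.
#' @export
correlation_long <- function(cm) {
  idx <- expand.grid(i = seq_len(nrow(cm$r)), j = seq_len(ncol(cm$r)))
  data.frame(trait1 = rownames(cm$r)[idx$i], trait2 = colnames(cm$r)[idx$j],
             r = cm$r[as.matrix(idx)], p = cm$p[as.matrix(idx)],
             n = cm$n[as.matrix(idx)], stringsAsFactors = FALSE)
}
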