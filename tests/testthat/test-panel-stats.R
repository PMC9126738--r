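test_that("Tukey fences exclude distant points under interpolated quartiles", {
  r <- tukey_filter(c(1, 2, 3, 4, 100))
  expect_equal(r$excluded, 100)       # Q1 = 2, Q3 = 4, upper fence = 7
  expect_equal(r$retained, c(1, 2, 3, 4))
  expect_equal(r$fences, c(-1, 7))
  expect_length(tukey_filter(rep(5, 10))$excluded, 0)
  x <- c(10, 11, 12, 13, 14)
  expect_equal(tukey_filter(x)$retained, x)  # symmetric data untouched
  few <- tukey_filter(c(1, 2, 100))
  expect_true(few$warning)
  expect_length(few$excluded, 0)
  # idempotence on the retained set
  r2 <- tukey_filter(r$retained)
  expect_equal(r2$retained, r$retained)
})

test_that("two-line cascade picks the right t-test flavour and matches closed forms", {
  set.seed(42)
  a <- rnorm(10, 10, 1); b <- rnorm(10, 13, 1)
  r <- compare_two_lines(a, b)
  expect_equal(r$flavour, "pooled")
  expect_lt(r$t_p, 0.01)
  # closed-form pooled t oracle
  sp2 <- ((9 * var(a) + 9 * var(b)) / 18)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 10 + 1 / 10))
  expect_equal(r$t_stat, t_oracle, tolerance = 1e-10)
  # 10x variance ratio forces Welch
  set.seed(43)
  a2 <- rnorm(10, 10, 1); b2 <- rnorm(10, 10, sqrt(10))
  r2 <- compare_two_lines(a2, b2)
  expect_equal(r2$flavour, "welch")
  t_welch <- (mean(a2) - mean(b2)) / sqrt(var(a2) / 10 + var(b2) / 10)
  expect_equal(r2$t_stat, t_welch, tolerance = 1e-10)
  # identical groups: zero mean difference, p at the numerical ceiling
  x <- c(1.2, 1.9, 3.1, 4.4)
  ri <- compare_two_lines(x, x)
  expect_equal(ri$mean_a, ri$mean_b)
  expect_gt(ri$t_p, 0.999)
  # degenerate variance flagged with NA p
  rd <- compare_two_lines(c(1, 1, 1), c(2, 3, 4))
  expect_true(rd$degenerate)
  expect_true(is.na(rd$t_p))
})

test_that("two-line cascade agrees with library oracles over random fixtures", {
  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(4:12, 1); n2 <- sample(4:12, 1)
    a <- rnorm(n1, 10, runif(1, 0.5, 2)); b <- rnorm(n2, 10.5, runif(1, 0.5, 2))
    r <- compare_two_lines(a, b)
    tt <- t.test(a, b, var.equal = var.test(a, b)$p.value > 0.05)
    expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$t_p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("adjusted genotype means reduce to raw means without a covariate effect and recover known contrasts", {
  set.seed(5)
  tab <- data.frame(genotype = rep(c("g1", "g2", "g3"), each = 8),
                    cov = rnorm(24))
  tab$y <- c(10, 12, 15)[as.integer(factor(tab$genotype))] + rnorm(24, 0, 0.3)
  m0 <- adjusted_genotype_means(tab, "y", "cov")
  raw <- tapply(tab$y, tab$genotype, mean)
  expect_length(attr(m0, "covariates_used"), 0)  # null covariate dropped
  expect_equal(m0$mean, as.vector(raw[m0$genotype]), tolerance = 1e-8)
  # covariate with slope 2: adjustment recovers the clean contrasts
  tab$y2 <- tab$y + 2 * tab$cov
  m1 <- adjusted_genotype_means(tab, "y2", "cov")
  expect_equal(attr(m1, "covariates_used"), "cov")
  d21 <- m1$mean[m1$genotype == "g2"] - m1$mean[m1$genotype == "g1"]
  expect_lt(abs(d21 - (raw[["g2"]] - raw[["g1"]])), 0.5)
  # single genotype: its mean
  one <- adjusted_genotype_means(tab[tab$genotype == "g1", ], "y")
  expect_equal(one$mean, mean(tab$y[tab$genotype == "g1"]))
  expect_match(attr(m1, "note"), "random")
})

test_that("correlation matrices match the cor.test oracle and are affine invariant", {
  set.seed(11)
  tab <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20))
  tab$y <- tab$x * 0.5 + tab$y
  cm <- correlation_matrix(tab)
  expect_equal(diag(cm$r), c(x = 1, y = 1, z = 1))
  expect_equal(cm$r, t(cm$r))
  for (pair in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    ct <- cor.test(tab[[pair[1]]], tab[[pair[2]]])
    expect_equal(cm$r[pair[1], pair[2]], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(cm$p[pair[1], pair[2]], ct$p.value, tolerance = 1e-10)
  }
  # exact linear dependence
  t3 <- data.frame(x = c(1, 2, 3), y = c(2, 4, 6))
  expect_equal(correlation_matrix(t3)$r["x", "y"], 1)
  # affine transformation of a trait leaves r untouched
  tab2 <- tab; tab2$y <- -3 * tab$y + 7
  cm2 <- correlation_matrix(tab2)
  expect_equal(abs(cm2$r["x", "y"]), abs(cm$r["x", "y"]), tolerance = 1e-12)
  # pairwise-complete with n per pair; n < 3 gives NA
  tab$w <- c(rnorm(2), rep(NA, 18))
  cm3 <- correlation_matrix(tab)
  expect_equal(cm3$n["x", "w"], 2)
  expect_true(is.na(cm3$r["x", "w"]))
})

test_that("cross-environment mode pairs genotypes and recovers a planted correlation", {
  set.seed(13)
  g <- sprintf("g%02d", 1:40)
  eff <- MASS::mvrnorm(40, c(0, 0), matrix(c(1, 0.6, 0.6, 1), 2))
  f <- data.frame(genotype = g, tr = 10 + eff[, 1], other = rnorm(40))
  gh <- data.frame(genotype = sample(g), stringsAsFactors = FALSE)
  gh$tr <- 10 + eff[match(gh$genotype, g), 2]
  gh$other <- rnorm(40)
  cm <- correlation_matrix(f, gh)
  se <- 1 / sqrt(40 - 3)
  expect_lt(abs(atanh(cm$r["tr", "tr"]) - atanh(0.6)), 2.5 * se)
  expect_lt(abs(cm$r["other", "other"]), 0.35)
})

test_that("type-I error of the correlation p-value is calibrated", {
  set.seed(17)
  hits <- 0; m <- 400
  for (i in seq_len(m)) {
    x <- rnorm(30); y <- rnorm(30)
    cm <- correlation_matrix(data.frame(x = x, y = y))
    hits <- hits + (cm$p["x", "y"] < 0.05)
  }
  expect_lt(abs(hits / m - 0.05), 0.03)
})
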