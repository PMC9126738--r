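# toy variant table used across tests: 12 Mbp chromosome, 4 sites
toy_vt <- function() {
  variant_table(data.frame(chrom = "chr1",
                           pos = c(1, 2e6, 6e6, 11e6),
                           S1 = c(0, 2, 1, 0),
                           S2 = c(0, 2, 1, 2)),
                contig_lengths = c(chr1 = 12e6))
}

test_that("bin tallies match the hand count on the toy chromosome", {
  b <- bin_ibs(toy_vt(), "S1", "S2")
  expect_equal(nrow(b), 3)
  expect_equal(b$bin_start, c(0, 5e6, 10e6))
  expect_equal(b$bin_end, c(5e6, 10e6, 12e6))  # terminal short bin kept
  expect_equal(b$n_sites, c(2, 1, 1))
  expect_equal(b$fraction, c(1, 1, 0))
})

test_that("IBS binning is symmetric, self-identical, and NA on missing data", {
  vt <- generate_variant_table(c(c1 = 8e6, c2 = 6e6), 2e-5, seed = 3)
  b_ab <- bin_ibs(vt, "LINE51", "LINE64")
  b_ba <- bin_ibs(vt, "LINE64", "LINE51")
  expect_equal(b_ab$fraction, b_ba$fraction)
  self <- bin_ibs(vt, "LINE51", "LINE51")
  expect_true(all(self$fraction[self$n_sites > 0] == 1))
  vtm <- toy_vt(); vtm$sites$S2 <- NA_real_
  bm <- bin_ibs(vtm, "S1", "S2")
  expect_true(all(is.na(bm$fraction)))
  expect_true(all(bm$n_sites == 0))
  expect_error(bin_ibs(vt, "LINE51", "nope"), "unknown sample")
})

test_that("missing-call sites are excluded from n_sites and counts are conserved", {
  vt <- toy_vt()
  vt$sites$S2[2] <- NA  # site at 2 Mbp now uncounted
  b <- bin_ibs(vt, "S1", "S2")
  expect_equal(b$n_sites, c(1, 1, 1))
  vt2 <- generate_variant_table(c(c1 = 9e6), 5e-5, seed = 4)
  b2 <- bin_ibs(vt2, "LINE51", "LINE64")
  expect_equal(sum(b2$n_sites), nrow(vt2$sites))  # no missing calls generated
})

test_that("variant filters use strict inequalities on missingness and MAF", {
  # 10 diploid samples; build sites hitting the boundaries exactly
  g_maf05 <- c(1, rep(0, 9))                     # minor count 1/20 = 0.05
  g_maf10 <- c(2, rep(0, 9))                     # 2/20 = 0.10
  g_miss10 <- c(NA, 1, 1, rep(0, 5), 2, 2)       # 1/10 missing = 0.10
  g_mono <- rep(0, 10)
  sites <- data.frame(chrom = "c1", pos = 1:4)
  for (i in 1:10) sites[[paste0("s", i)]] <-
    c(g_maf05[i], g_maf10[i], g_miss10[i], g_mono[i])
  vt <- variant_table(sites)
  f <- filter_variants(vt)
  expect_equal(f$sites$pos, 2L)            # only the MAF = 0.10 site survives
  expect_equal(attr(f, "n_removed"), 3L)
  # relaxing the thresholds readmits the boundary sites
  f2 <- filter_variants(vt, max_missing = 0.11, min_maf = 0.04)
  expect_setequal(f2$sites$pos, c(1L, 2L, 3L))
})

test_that("filtering commutes with binning", {
  vt <- generate_variant_table(c(c1 = 6e6), 1e-4, seed = 9, het_rate = 0.3,
                               default_prob = 0.7)
  # extra samples so MAF filtering is meaningful: duplicate with mutations
  s <- vt$sites
  set.seed(9)
  for (nm in c("X1", "X2", "X3")) s[[nm]] <- sample(c(0, 1, 2), nrow(s), TRUE)
  vt5 <- variant_table(s, vt$contig_lengths)
  f_then_b <- bin_ibs(filter_variants(vt5), "LINE51", "LINE64")
  keep <- filter_variants(vt5)$sites$pos
  vt_sub <- variant_table(vt5$sites[vt5$sites$pos %in% keep, ], vt5$contig_lengths)
  b_of_sub <- bin_ibs(vt_sub, "LINE51", "LINE64")
  expect_equal(f_then_b$fraction, b_of_sub$fraction)
  expect_equal(f_then_b$n_sites, b_of_sub$n_sites)
})

test_that("allele-sharing mode scores hets against homs as half", {
  vt <- toy_vt()
  b <- bin_ibs(vt, "S1", "S2", mode = "allele")
  # last site: 0 vs 2 -> sharing 0; site 3: 1 vs 1 -> 1
  expect_equal(b$fraction, c(1, 1, 0))
  vt$sites$S2[3] <- 0  # het vs hom-ref -> 0.5
  b2 <- bin_ibs(vt, "S1", "S2", mode = "allele")
  expect_equal(b2$fraction[2], 0.5)
})

test_that("chromosome summaries report threshold percentages and spanned length", {
  b <- bin_ibs(toy_vt(), "S1", "S2")
  s <- chromosome_summary(b)
  expect_equal(s$per_chromosome$pct_above_hi, 100 * 2 / 3)
  expect_equal(s$per_chromosome$pct_below_lo, 100 * 1 / 3)
  expect_equal(s$total_bp_above_hi, 1e7)
  # synthetic genome with 75% high-similarity region recovers ~75%
  prof <- data.frame(chrom = "c1", start = c(0, 15e6), end = c(15e6, 20e6),
                     ibs_prob = c(0.97, 0.05))
  vt <- generate_variant_table(c(c1 = 20e6), 1e-4, prof, seed = 21)
  sm <- chromosome_summary(bin_ibs(vt, "LINE51", "LINE64"))
  expect_equal(sm$per_chromosome$pct_above_hi, 75, tolerance = 0.35)
  # chromosome of only empty bins
  vt_e <- variant_table(data.frame(chrom = "c9", pos = 1, A = NA_real_, B = NA_real_),
                        c(c9 = 7e6))
  se <- chromosome_summary(bin_ibs(vt_e, "A", "B"))
  expect_true(is.na(se$per_chromosome$pct_above_hi))
})

test_that("VCF round trip preserves calls and contig lengths", {
  vt <- generate_variant_table(c(c1 = 4e6, c2 = 3e6), 5e-5, seed = 12,
                               het_rate = 0.1, default_prob = 0.8)
  path <- tempfile(fileext = ".vcf")
  write_vcf(vt, path)
  vt2 <- read_variants(path)
  expect_equal(vt2$samples, vt$samples)
  expect_equal(vt2$contig_lengths, vt$contig_lengths)
  expect_equal(vt2$sites$pos, vt$sites$pos)
  expect_equal(vt2$sites$LINE51, vt$sites$LINE51)
  expect_equal(vt2$sites$LINE64, vt$sites$LINE64)
  b1 <- bin_ibs(vt, "LINE51", "LINE64")
  b2 <- bin_ibs(vt2, "LINE51", "LINE64")
  expect_equal(b1$fraction, b2$fraction)
})
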