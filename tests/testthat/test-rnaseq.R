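# FPKM, RES, the chi-square differential test, abundance quotients, 2^-ddCt.

test_that("fpkm matches its closed form and is linear in counts", {
  expect_identical(fpkm(100, 1000, 1e6), 100)
  expect_identical(fpkm(0, 2000, 1e7), 0)
  expect_equal(fpkm(10, 2000, 2e7), 0.25, tolerance = 1e-12)
  # linearity / inverse proportionality
  expect_equal(fpkm(30, 1000, 1e6), 3 * fpkm(10, 1000, 1e6))
  expect_equal(fpkm(10, 2000, 1e6), fpkm(10, 1000, 1e6) / 2)
  expect_equal(fpkm(10, 1000, 2e6), fpkm(10, 1000, 1e6) / 2)
  expect_error(fpkm(1, 0, 1e6), class = "estdigex_error_domain")
  expect_error(fpkm(-1, 10, 1e6), class = "estdigex_error_negative_count")
})

test_that("RES follows its formula with canonical tie-breaking", {
  r <- res_specificity(10, c(ROOT = 2, LEAF = 5, STEM = 1))
  expect_equal(r$res, 0.5)
  expect_equal(r$tissue_b, "LEAF")
  expect_true(r$defined)
  # exclusive expression
  expect_equal(res_specificity(10, c(ROOT = 0, LEAF = 0))$res, 1)
  # negative specificity
  expect_equal(res_specificity(5, c(ROOT = 10))$res, -1)
  # undefined at zero focal expression
  r0 <- res_specificity(0, c(ROOT = 1))
  expect_false(r0$defined)
  expect_true(is.na(r0$res))
  # tie in B broken by canonical tissue order (STAMEN before ROOT)
  tie <- res_specificity(10, c(ROOT = 5, STAMEN = 5))
  expect_equal(tie$tissue_b, "STAMEN")
  expect_error(res_specificity(1, numeric(0)),
               class = "estdigex_error_empty_comparison")
})

test_that("RES is invariant to rescaling all expression values", {
  set.seed(5)
  for (i in 1:20) {
    vals <- stats::runif(4, 0, 50)
    a <- stats::runif(1, 0.1, 50)
    c0 <- res_specificity(a, c(ROOT = vals[1], LEAF = vals[2],
                               STEM = vals[3], GRAIN = vals[4]))
    ck <- res_specificity(7.3 * a, 7.3 * c(ROOT = vals[1], LEAF = vals[2],
                                           STEM = vals[3], GRAIN = vals[4]))
    expect_equal(c0$res, ck$res, tolerance = 1e-12)
  }
})

# textbook Pearson statistic: independent oracle for chi_square_diff
pearson_oracle <- function(a, da, b, db) {
  tab <- matrix(c(a, da - a, b, db - b), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

test_that("chi-square test matches the Pearson oracle and spot values", {
  same <- chi_square_diff(10, 1000, 10, 1000)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  ct <- chi_square_diff(30, 1000, 10, 1000)
  expect_equal(ct$statistic, pearson_oracle(30, 1000, 10, 1000),
               tolerance = 1e-10)
  expect_equal(ct$df, 1L)
  expect_true(ct$significant)

  set.seed(31)
  for (i in 1:50) {
    da <- sample(100:5000, 1); db <- sample(100:5000, 1)
    a <- sample(0:50, 1); b <- sample(0:50, 1)
    if (a + b == 0) a <- 1
    got <- chi_square_diff(a, da, b, db)
    expect_equal(got$statistic, pearson_oracle(a, da, b, db),
                 tolerance = 1e-8)
    expect_equal(got$p_value,
                 stats::pchisq(got$statistic, df = 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("chi-square test is symmetric and strict at the alpha boundary", {
  x <- chi_square_diff(25, 2000, 9, 1500)
  y <- chi_square_diff(9, 1500, 25, 2000)
  expect_equal(x$statistic, y$statistic, tolerance = 1e-12)
  # construct a table with p exactly alpha: significance requires strict <
  stat_alpha <- stats::qchisq(0.95, df = 1)
  r <- chi_square_diff(10, 1000, 10, 1000,
                       alpha = 1)  # p = 1 < alpha would be TRUE at alpha > 1
  expect_false(chi_square_diff(10, 1000, 10, 1000, alpha = 1)$significant)
  expect_error(chi_square_diff(1, 0, 1, 10), class = "estdigex_error_domain")
})

test_that("degenerate tables with both proportions 0 or 1 return p = 1", {
  z <- chi_square_diff(0, 1000, 0, 2000)
  expect_equal(c(z$statistic, z$p_value), c(0, 1))
  full <- chi_square_diff(1000, 1000, 2000, 2000)
  expect_equal(c(full$statistic, full$p_value), c(0, 1))
})

test_that("the Yates-corrected variant differs and is available", {
  plain <- chi_square_diff(30, 1000, 10, 1000)
  yates <- chi_square_diff(30, 1000, 10, 1000, correct = TRUE)
  expect_lt(yates$statistic, plain$statistic)
})

test_that("2^-ddCt fold change is exact", {
  expect_identical(ddct_fold_change(0), 1)
  expect_identical(ddct_fold_change(-1), 2)
  expect_equal(ddct_fold_change(log2(10)), 0.1, tolerance = 1e-8)
})

test_that("relative abundance uses max-over-stages and the log floor", {
  ex <- validate_expression_table(tibble::tibble(
    gene_id = "g1",
    tissue = c("ROOT", "ROOT", "ROOT", "LEAF"),
    stage = c("T1", "T2", "T3", "T1"),
    raw_count = c(20L, 50L, 30L, 0L),
    mapped_total = 1e7L,
    gene_length_bp = 1000
  ))
  ra <- relative_abundance(ex)
  root <- ra[ra$tissue == "ROOT", ]
  expect_equal(root$fpkm, 5)  # the maximal stage (50 reads -> FPKM 5)
  mean_fpkm <- mean(c(5, 0))
  expect_equal(root$log_quotient, log2(5 / mean_fpkm + 0.01),
               tolerance = 1e-12)
  leaf <- ra[ra$tissue == "LEAF", ]
  expect_equal(leaf$log_quotient, log2(0.01), tolerance = 1e-12)
})

test_that("abundance quotient is ~0 on the log scale at the gene-set mean", {
  ex <- toy_expression(
    profile_rows("g1", stamen = 10, root = 10, leaf = 10, pistil = 10,
                 inflorescence = 10, stem = 10, grain = 10))
  ra <- relative_abundance(ex)
  expect_true(all(abs(ra$log_quotient - log2(1.01)) < 1e-12))
})

test_that("profile_expression reports RES, B, and the chi-square call", {
  ex <- toy_expression(
    profile_rows("g1", stamen = 40, pistil = 5, root = 1,
                 inflorescence = 2),
    profile_rows("g2", stamen = 0, pistil = 8, root = 8,
                 inflorescence = 1)
  )
  pr <- profile_expression(ex, focal = "STAMEN")
  g1 <- pr[pr$gene_id == "g1", ]
  expect_equal(g1$tissue_b, "PISTIL")
  expect_equal(g1$res, (40 - 5) / 40)
  expect_true(g1$significant)
  g2 <- pr[pr$gene_id == "g2", ]
  expect_false(g2$defined)
})
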