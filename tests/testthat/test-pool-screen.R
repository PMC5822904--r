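# The sampling-probability statistic and the screening decision rules.

test_that("pool_est_frequency is exact division with guarded domain", {
  expect_identical(pool_est_frequency(10, 100000), 1e-4)
  expect_identical(pool_est_frequency(0, 50000), 0)
  expect_identical(pool_est_frequency(50000, 50000), 1)
  expect_error(pool_est_frequency(1, 0),
               class = "estdigex_error_undefined_frequency")
  expect_error(pool_est_frequency(5, 3), class = "estdigex_error_domain")
})

test_that("sampling probability matches closed-form spot values", {
  # 0^0 convention and certain events
  expect_identical(sampling_probability(0, 100, 0), 1)
  expect_identical(sampling_probability(10, 10, 1), 1)
  expect_identical(sampling_probability(3, 100, 0), 0)
  expect_identical(sampling_probability(9, 10, 1), 0)
  # 0.999^1000
  expect_equal(sampling_probability(0, 1000, 0.001), 0.999^1000,
               tolerance = 1e-12)
  # 45 * 0.01 * 0.9^8
  expect_equal(sampling_probability(2, 10, 0.1), 45 * 0.01 * 0.9^8,
               tolerance = 1e-12)
  expect_error(sampling_probability(11, 10, 0.5),
               class = "estdigex_error_domain")
  expect_error(sampling_probability(1, 10, 1.5),
               class = "estdigex_error_domain")
})

test_that("sampling probability matches the frozen high-precision oracle", {
  oracle <- readr::read_tsv(test_path("fixtures", "binom-oracle.tsv"),
                            show_col_types = FALSE)
  lp <- sampling_probability(oracle$n, oracle$N, oracle$f, log = TRUE)
  expect_lt(max(abs(lp - oracle$log_p)), 1e-9)
})

test_that("sampling probability agrees with dbinom and sums to one", {
  set.seed(11)
  for (i in 1:25) {
    N <- sample(1:5000, 1)
    n <- sample(0:N, 1)
    f <- stats::runif(1)
    expect_equal(sampling_probability(n, N, f), stats::dbinom(n, N, f),
                 tolerance = 1e-12)
  }
  for (N in c(1, 7, 50, 200)) {
    for (f in c(1e-4, 0.02, 0.37, 0.5)) {
      expect_lt(abs(sum(sampling_probability(0:N, N, f)) - 1), 1e-10)
    }
  }
})

test_that("tail-sum variant is the lower-tail cumulative", {
  expect_equal(sampling_probability(3, 20, 0.2, tail_sum = TRUE),
               sum(sampling_probability(0:3, 20, 0.2)), tolerance = 1e-12)
})

make_pools <- function(m, M, root = c(0, 30000), stem = c(0, 30000),
                       leaf = c(0, 30000), seed = c(0, 30000)) {
  tibble::tibble(
    pool = c("INFLORESCENCE", "ROOT", "STEM", "LEAF", "SEED"),
    n = as.integer(c(m, root[1], stem[1], leaf[1], seed[1])),
    N = as.integer(c(M, root[2], stem[2], leaf[2], seed[2]))
  )
}

test_that("screen_gene routes SOLE, SIGNIFICANT and FAIL correctly", {
  sole <- screen_gene(make_pools(15, 30000), threshold = 1e-4)
  expect_equal(sole$route, "SOLE")
  expect_true(sole$passes)

  none <- screen_gene(make_pools(0, 30000), threshold = 1e-4)
  expect_equal(none$route, "FAIL")

  # f = 2e-4, leaf n = 5 of 50000: P ~ 0.0378 > 1e-4 -> FAIL at tier 1
  rec <- screen_gene(make_pools(20, 100000, leaf = c(5, 50000)),
                     threshold = 1e-4)
  expect_equal(rec$P_leaf, dbinom(5, 50000, 2e-4), tolerance = 1e-10)
  expect_gt(rec$P_leaf, 1e-4)
  expect_equal(rec$route, "FAIL")
  # cross-check magnitude with the Poisson approximation at lambda = 10
  expect_equal(rec$P_leaf, dpois(5, 10), tolerance = 0.01)
})

test_that("empty pools never block a pass", {
  rec <- screen_gene(make_pools(15, 30000, stem = c(0, 0)), threshold = 1e-4)
  expect_true(rec$passes)
  expect_true(is.na(rec$P_stem))
})

test_that("a gene can pass the looser tier-2 threshold only", {
  # choose counts whose P lies in (1e-4, 0.01]: m=60/M=100000 (f=6e-4),
  # root n=8 of 30000: expected 18, dbinom(8, 30000, 6e-4) ~ 0.0035
  p <- dbinom(8, 30000, 6e-4)
  expect_true(p > 1e-4 && p <= 0.01)
  pools <- make_pools(60, 100000, root = c(8, 30000))
  expect_false(screen_gene(pools, threshold = 1e-4)$passes)
  expect_true(screen_gene(pools, threshold = 0.01)$passes)
})

test_that("raising the threshold never turns a pass into a fail", {
  set.seed(21)
  thresholds <- c(1e-6, 1e-4, 1e-2, 0.5)
  for (i in 1:30) {
    m <- sample(0:50, 1)
    pools <- make_pools(m, 50000,
                        root = c(sample(0:10, 1), 30000),
                        stem = c(sample(0:10, 1), 30000),
                        leaf = c(sample(0:10, 1), 30000),
                        seed = c(sample(0:10, 1), 30000))
    passed <- vapply(thresholds,
                     function(t) screen_gene(pools, threshold = t)$passes,
                     logical(1))
    expect_true(all(diff(passed) >= 0))
  }
})

test_that("SOLE route is threshold-independent", {
  pools <- make_pools(4, 30000)
  for (t in c(1e-10, 1e-4, 0.5)) {
    expect_equal(screen_gene(pools, threshold = t)$route, "SOLE")
  }
})

test_that("directionality guard blocks overrepresented pools", {
  # root frequency far ABOVE f: point pmf can still be tiny, but the gene is
  # not inflorescence-enriched
  pools <- make_pools(5, 100000, root = c(200, 30000))
  expect_false(screen_gene(pools, threshold = 0.5)$passes)
  guardless <- screen_gene(pools, threshold = 0.999999,
                           direction_guard = FALSE)
  expect_true(guardless$passes)
})

test_that("run_screen is deterministic, ordered, and tier-aware", {
  m <- toy_matrix()
  libs <- toy_libraries()
  rec <- run_screen(m, libs)
  expect_s3_class(rec, "estdigex_screen")
  expect_equal(rec$gene_id, m$gene_id)
  expect_equal(rec$tier[1], "contig_90")
  expect_equal(attr(rec, "threshold"), 1e-4)
  expect_identical(tibble::as_tibble(rec), tibble::as_tibble(run_screen(m, libs)))
  # exactly gene1 passes (sole inflorescence)
  expect_equal(rec$gene_id[rec$passes], "gene1")
  expect_equal(rec$route[1], "SOLE")
  g <- glance(rec)
  expect_equal(g$n_sole, 1L)
  expect_equal(g$n_tested, 3L)
})

test_that("merged-pool option tests one combined pool", {
  m <- toy_matrix()
  rec <- run_screen(m, toy_libraries(), merged_pool = TRUE)
  expect_true("P_merged" %in% names(rec))
  expect_equal(rec$gene_id[rec$passes], "gene1")
})
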