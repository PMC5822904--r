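# Library metadata, count-matrix and expression-table construction, the
# inclusion filter, TSV round-trips, and tissue pooling.

test_that("library filter drops small and normalized libraries, keeps order", {
  libs <- est_libraries(
    c("a", "b", "c", "d"),
    c("root", "root", "leaf", "anther"),
    c(999, 1000, 5000, 5000),
    c(FALSE, FALSE, FALSE, TRUE)
  )
  kept <- filter_libraries(libs)
  expect_equal(kept$library_id, c("b", "c"))
  # idempotent
  expect_identical(filter_libraries(kept), kept)
  # vacuous case
  expect_equal(nrow(filter_libraries(libs[0, ])), 0L)
})

test_that("tissue aliases resolve to the five pool classes, unknowns error", {
  libs <- est_libraries(c("x", "y", "z"), c("anther", "Pistil", "palea"),
                        c(2000, 2000, 2000), c(0, 0, 0))
  expect_equal(unique(libs$tissue_class), "INFLORESCENCE")
  expect_error(
    est_libraries("w", "mystery organ", 2000, FALSE),
    class = "estdigex_error_unknown_tissue"
  )
})

test_that("count matrices validate cells against library sizes", {
  libs <- toy_libraries()
  expect_error(
    est_count_matrix(
      tibble::tibble(gene_id = "g", inf1 = -1L),
      tier = "contig_90"),
    class = "estdigex_error_negative_count"
  )
  expect_error(
    est_count_matrix(
      tibble::tibble(gene_id = "g", inf1 = 10001L),
      tier = "contig_90", libraries = libs),
    class = "estdigex_error_count_exceeds_total"
  )
  expect_error(
    est_count_matrix(
      tibble::tibble(gene_id = "g", nosuchlib = 1L),
      tier = "contig_90", libraries = libs),
    class = "estdigex_error_missing_library"
  )
  expect_error(
    est_count_matrix(tibble::tibble(other = "g", inf1 = 1L), "contig_90"),
    class = "estdigex_error_malformed_header"
  )
})

test_that("TSV round-trips are exact for all three tables", {
  dir <- withr::local_tempdir()
  libs <- toy_libraries()
  write_library_table(libs, file.path(dir, "libs.tsv"))
  expect_equal(read_library_table(file.path(dir, "libs.tsv")), libs)

  m <- toy_matrix()
  write_count_matrix(m, file.path(dir, "counts.tsv"))
  m2 <- read_count_matrix(file.path(dir, "counts.tsv"), tier = "contig_90",
                          libraries = libs)
  expect_equal(tibble::as_tibble(m2), tibble::as_tibble(m))
  expect_equal(matrix_tier(m2), "contig_90")

  ex <- toy_expression(profile_rows("g1", stamen = 12.5, leaf = 3))
  write_expression_table(ex, file.path(dir, "expr.tsv"))
  ex2 <- read_expression_table(file.path(dir, "expr.tsv"))
  expect_equal(ex2$fpkm, ex$fpkm, tolerance = 1e-6)
  expect_equal(ex2$raw_count, ex$raw_count)
})

test_that("pool_counts aggregates by tissue class and conserves counts", {
  pooled <- pool_counts(toy_matrix(), toy_libraries())
  g1 <- pooled[pooled$gene_id == "gene1", ]
  infl <- g1[g1$pool == "INFLORESCENCE", ]
  expect_equal(infl$n, 10L)          # 3 + 7 over two inflorescence libraries
  expect_equal(infl$N, 30000L)       # 10000 + 20000
  # absent gene: all zero
  g3 <- pooled[pooled$gene_id == "gene3", ]
  expect_true(all(g3$n == 0L))
  # count conservation: pool sums equal row sums of the matrix
  m <- toy_matrix()
  row_totals <- rowSums(as.matrix(tibble::as_tibble(m)[-1]))
  pool_totals <- tapply(pooled$n, pooled$gene_id, sum)
  expect_equal(as.vector(pool_totals[m$gene_id]), unname(row_totals))
})

test_that("pool_counts reports empty pools as n = 0, N = 0", {
  libs <- toy_libraries()[1:3, ]  # no stem/leaf/seed libraries
  m <- est_count_matrix(
    tibble::tibble(gene_id = "g", inf1 = 2L, inf2 = 1L, root1 = 0L),
    tier = "contig_90", libraries = libs)
  pooled <- pool_counts(m, libs)
  stem <- pooled[pooled$pool == "STEM", ]
  expect_equal(c(stem$n, stem$N), c(0L, 0L))
})

test_that("pool_counts is invariant to library column order", {
  m <- toy_matrix()
  shuffled <- est_count_matrix(
    tibble::as_tibble(m)[, c("gene_id", "seed1", "inf2", "leaf1", "root1",
                             "stem1", "inf1")],
    tier = "contig_90", libraries = toy_libraries())
  a <- pool_counts(m, toy_libraries())
  b <- pool_counts(shuffled, toy_libraries())
  expect_equal(dplyr::arrange(a, gene_id, pool),
               dplyr::arrange(b, gene_id, pool))
})

test_that("pool_counts rejects unknown genes and unknown libraries", {
  expect_error(pool_counts(toy_matrix(), toy_libraries(), gene_id = "nope"),
               class = "estdigex_error_unknown_gene")
  expect_error(pool_counts(toy_matrix(), toy_libraries()[-1, ]),
               class = "estdigex_error_missing_library")
})

test_that("expression table validation flags bad rows", {
  rows <- profile_rows("g", stamen = 5)
  rows$raw_count[2] <- rows$mapped_total[2] + 1L
  expect_error(validate_expression_table(rows),
               class = "estdigex_error_negative_count")
  rows2 <- profile_rows("g", stamen = 5)
  rows2$tissue[1] <- "ANTHER"
  expect_error(validate_expression_table(rows2),
               class = "estdigex_error_unknown_tissue")
})
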