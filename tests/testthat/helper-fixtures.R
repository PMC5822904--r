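# Shared in-code fixtures: tiny libraries, count matrices and expression
# tables built deterministically.

toy_libraries <- function() {
  est_libraries(
    library_id = c("inf1", "inf2", "root1", "stem1", "leaf1", "seed1"),
    tissue     = c("anther", "spike", "root", "stem", "leaf", "embryo"),
    est_total  = c(10000, 20000, 30000, 5000, 40000, 25000),
    normalized = rep(FALSE, 6)
  )
}

# gene1: inflorescence-only; gene2: flat background; gene3: absent
toy_matrix <- function(tier = "contig_90") {
  est_count_matrix(
    tibble::tibble(
      gene_id = c("gene1", "gene2", "gene3"),
      inf1 = c(3L, 2L, 0L), inf2 = c(7L, 4L, 0L),
      root1 = c(0L, 6L, 0L), stem1 = c(0L, 1L, 0L),
      leaf1 = c(0L, 8L, 0L), seed1 = c(0L, 5L, 0L)
    ),
    tier = tier, libraries = toy_libraries()
  )
}

# One-stage-per-tissue expression rows with exact (noise-free) counts:
# raw_count = fpkm * length * depth / 1e9, integral for depth 1e7, len 1000.
profile_rows <- function(gene_id, inflorescence = 0, stamen = 0, pistil = 0,
                         root = 0, leaf = 0, stem = 0, grain = 0,
                         depth = 1e7, len = 1000) {
  vals <- c(INFLORESCENCE = inflorescence, STAMEN = stamen, PISTIL = pistil,
            ROOT = root, LEAF = leaf, STEM = stem, GRAIN = grain)
  tibble::tibble(
    gene_id = gene_id,
    tissue = names(vals),
    stage = c("Z32", "S1", "S1", "T1", "T1", "T1", "T1"),
    raw_count = as.integer(round(vals * len * depth / 1e9)),
    mapped_total = as.integer(depth),
    gene_length_bp = len
  )
}

toy_expression <- function(...) {
  validate_expression_table(dplyr::bind_rows(...))
}
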