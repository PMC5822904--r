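# EST library metadata, count matrices, expression tables: constructors,
# validators, TSV readers/writers, the library-inclusion filter and pooling.

#' Construct and validate an EST library metadata table
#'
#' One row per cDNA library: the sampling unit of the digital expression
#' screen. `tissue` may be a free-text alias (resolved through `aliases`) or
#' one of the five canonical pool classes.
#'
#' @param library_id Character, unique library identifiers.
#' @param tissue Character, tissue descriptions or canonical classes.
#' @param est_total Non-negative integers: number of ESTs (cloning events).
#' @param normalized Logical (or 0/1): was the library subjected to
#'   normalization or enrichment treatment?
#' @param aliases Alias table, see [tissue_alias_table()].
#' @return A tibble with columns `library_id`, `tissue_class`, `est_total`,
#'   `normalized`.
#' @export
#' @examples
#' est_libraries(c("L1", "L2"), c("anther", "root"), c(5000, 12000), c(0, 0))
est_libraries <- function(library_id, tissue, est_total, normalized,
                          aliases = tissue_alias_table()) {
  if (anyDuplicated(library_id)) {
    abort("library_id values must be unique",
          class = "estdigex_error_duplicate_library")
  }
  est_total <- as.integer(est_total)
  if (any(is.na(est_total)) || any(est_total < 0)) {
    abort("est_total must be a non-negative integer for every library",
          class = "estdigex_error_negative_count")
  }
  tibble(
    library_id   = as.character(library_id),
    tissue_class = resolve_tissue_alias(tissue, aliases),
    est_total    = est_total,
    normalized   = as.logical(normalized)
  )
}

#' Filter cDNA libraries for inclusion in the expression screen
#'
#' Libraries with fewer than `min_ests` ESTs, and libraries subjected to
#' normalization or enrichment treatment, are excluded: both distort the
#' relationship between EST counts and transcript abundance that the
#' sampling-probability statistic relies on. Order is preserved and the
#' operation is idempotent.
#'
#' @param libraries A library table from [est_libraries()] or
#'   [read_library_table()].
#' @param min_ests Minimum library size retained (default 1000).
#' @return The retained rows, same columns and order.
#' @export
#' @examples
#' libs <- est_libraries(c("a", "b"), c("root", "root"), c(999, 1000), c(0, 0))
#' filter_libraries(libs)
filter_libraries <- function(libraries, min_ests = 1000) {
  dplyr::filter(libraries, .data$est_total >= min_ests, !.data$normalized)
}

#' Read and write library metadata TSV
#'
#' Dialect: header `library_id  tissue  est_total  normalized` (tab-separated;
#' `tissue` free-text alias, `normalized` 0/1).
#'
#' @param path File path.
#' @param aliases Alias table, see [tissue_alias_table()].
#' @return `read_library_table()`: a validated library tibble.
#' @export
read_library_table <- function(path, aliases = tissue_alias_table()) {
  df <- read_tsv_checked(path, c("library_id", "tissue", "est_total",
                                 "normalized"))
  est_libraries(df$library_id, df$tissue, df$est_total,
                df$normalized != 0, aliases = aliases)
}

#' @rdname read_library_table
#' @param libraries Library tibble to write.
#' @export
write_library_table <- function(libraries, path) {
  out <- tibble(
    library_id = libraries$library_id,
    tissue     = libraries$tissue_class,
    est_total  = libraries$est_total,
    normalized = as.integer(libraries$normalized)
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Construct an EST count matrix at a homology tier
#'
#' A gene-by-library table of matched-EST counts. The `tier` records which
#' homology stage of the screen the counts come from: `"contig_90"` for the
#' first pass (ESTs matching assembled contigs at >= 90% identity) or
#' `"cds_99"` for the confirmation pass against predicted coding sequences at
#' >= 99% identity. Homology matching itself is upstream of this package; the
#' tier is a label carried through to the screen output.
#'
#' @param counts A data frame: first column `gene_id`, remaining columns one
#'   per library, integer matched-EST counts.
#' @param tier `"contig_90"` or `"cds_99"`.
#' @param libraries Optional library table; when supplied, every count column
#'   must name a known library and no count may exceed its library's
#'   `est_total`.
#' @return A tibble of class `est_count_matrix` with a `tier` attribute.
#' @export
est_count_matrix <- function(counts, tier = c("contig_90", "cds_99"),
                             libraries = NULL) {
  tier <- match.arg(tier)
  counts <- as_tibble(counts)
  if (names(counts)[1] != "gene_id") {
    abort("first column of a count matrix must be gene_id",
          class = "estdigex_error_malformed_header")
  }
  if (anyDuplicated(counts$gene_id)) {
    abort("gene_id values must be unique",
          class = "estdigex_error_duplicate_gene")
  }
  lib_cols <- names(counts)[-1]
  mat <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  if (anyNA(mat) || any(mat < 0)) {
    idx <- which(is.na(mat) | mat < 0, arr.ind = TRUE)[1, ]
    abort(
      sprintf("negative or missing count at gene '%s', library '%s'",
              counts$gene_id[idx[1]], lib_cols[idx[2]]),
      class = "estdigex_error_negative_count"
    )
  }
  if (!is.null(libraries)) {
    missing <- setdiff(lib_cols, libraries$library_id)
    if (length(missing)) {
      abort(paste0("count matrix libraries absent from metadata: ",
                   paste(missing, collapse = ", ")),
            class = "estdigex_error_missing_library")
    }
    totals <- libraries$est_total[match(lib_cols, libraries$library_id)]
    over <- which(t(mat) > totals, arr.ind = TRUE)  # t(): recycle by library
    if (length(over)) {
      abort(
        sprintf("count exceeds library size at gene '%s', library '%s'",
                counts$gene_id[over[1, 2]], lib_cols[over[1, 1]]),
        class = "estdigex_error_count_exceeds_total"
      )
    }
  }
  counts[-1] <- as_tibble(mat)
  structure(counts, tier = tier,
            class = c("est_count_matrix", class(counts)))
}

#' Homology tier of a count matrix
#' @param x An `est_count_matrix`.
#' @return `"contig_90"` or `"cds_99"`.
#' @export
matrix_tier <- function(x) attr(x, "tier")

#' Read and write count matrix TSV
#'
#' Dialect: first column `gene_id`, one integer column per library.
#'
#' @param path File path.
#' @param tier Homology tier label, see [est_count_matrix()].
#' @param libraries Optional library table for cross-validation.
#' @return `read_count_matrix()`: an `est_count_matrix`.
#' @export
read_count_matrix <- function(path, tier = c("contig_90", "cds_99"),
                              libraries = NULL) {
  df <- read_tsv_checked(path, "gene_id", exact = FALSE)
  est_count_matrix(df, tier = match.arg(tier), libraries = libraries)
}

#' @rdname read_count_matrix
#' @param matrix An `est_count_matrix` to write.
#' @export
write_count_matrix <- function(matrix, path) {
  readr::write_tsv(as_tibble(matrix), path)
  invisible(path)
}

#' Read and write a long-form RNA-seq expression table
#'
#' Dialect: `gene_id  tissue  stage  raw_count  mapped_total  gene_length_bp`
#' (tab-separated). Tissues use the seven-tissue RNA-seq vocabulary
#' ([rnaseq_tissues()]). FPKM is computed on read and returned as an extra
#' column; it is derived, not stored.
#'
#' @param path File path.
#' @return `read_expression_table()`: a tibble with the six stored columns
#'   plus `fpkm`.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "tissue", "stage", "raw_count",
                                 "mapped_total", "gene_length_bp"))
  validate_expression_table(df)
}

#' @rdname read_expression_table
#' @param expression Expression tibble to write (the `fpkm` column, if
#'   present, is dropped: it is recomputable).
#' @export
write_expression_table <- function(expression, path) {
  keep <- c("gene_id", "tissue", "stage", "raw_count", "mapped_total",
            "gene_length_bp")
  readr::write_tsv(expression[keep], path)
  invisible(path)
}

#' Validate an in-memory expression table
#'
#' Enforces the expression-table invariants (known tissues, non-negative
#' counts not exceeding the sample's mapped total, positive lengths and
#' depths) and appends the `fpkm` column.
#'
#' @param df Data frame with the six expression-table columns.
#' @return A validated tibble with `fpkm` added.
#' @export
validate_expression_table <- function(df) {
  df <- as_tibble(df)
  bad_tissue <- setdiff(unique(df$tissue), rnaseq_tissues())
  if (length(bad_tissue)) {
    abort(paste0("unknown RNA-seq tissue(s): ",
                 paste(bad_tissue, collapse = ", ")),
          class = "estdigex_error_unknown_tissue")
  }
  if (any(df$raw_count < 0 | df$raw_count > df$mapped_total)) {
    i <- which(df$raw_count < 0 | df$raw_count > df$mapped_total)[1]
    abort(sprintf("invalid raw_count at gene '%s', %s/%s",
                  df$gene_id[i], df$tissue[i], df$stage[i]),
          class = "estdigex_error_negative_count")
  }
  if (any(df$mapped_total <= 0) || any(df$gene_length_bp <= 0)) {
    abort("mapped_total and gene_length_bp must be positive",
          class = "estdigex_error_domain")
  }
  df$fpkm <- fpkm(df$raw_count, df$gene_length_bp, df$mapped_total)
  df
}

#' Pool matched-EST counts by tissue class
#'
#' Aggregates a count matrix over the retained libraries of each tissue
#' class. For every gene the inflorescence pool supplies the matched count
#' `m` and pool size `M` from which the EST frequency `f = m/M` is estimated;
#' each of the four non-inflorescence pools supplies an (`n`, `N`) pair for
#' the sampling-probability test. A tissue class with no libraries is
#' reported with `n = 0, N = 0`; downstream screening treats empty pools as
#' carrying no evidence either way.
#'
#' @param matrix An [est_count_matrix()].
#' @param libraries Library metadata covering every matrix column.
#' @param gene_id Optional single gene; default all genes.
#' @return A tibble `gene_id, pool, n, N` with one row per gene and tissue
#'   class (the `INFLORESCENCE` row holds `m`, `M`).
#' @export
pool_counts <- function(matrix, libraries, gene_id = NULL) {
  lib_cols <- names(matrix)[-1]
  missing <- setdiff(lib_cols, libraries$library_id)
  if (length(missing)) {
    abort(paste0("count matrix libraries absent from metadata: ",
                 paste(missing, collapse = ", ")),
          class = "estdigex_error_missing_library")
  }
  genes <- matrix$gene_id
  if (!is.null(gene_id)) {
    if (!gene_id %in% genes) {
      abort(sprintf("gene '%s' not present in count matrix", gene_id),
            class = "estdigex_error_unknown_gene")
    }
    matrix <- matrix[genes == gene_id, , drop = FALSE]
    genes <- gene_id
  }
  cls <- libraries$tissue_class[match(lib_cols, libraries$library_id)]
  totals <- libraries$est_total[match(lib_cols, libraries$library_id)]
  pools <- est_tissue_classes()
  mat <- as.matrix(matrix[, -1, drop = FALSE])
  # sum counts and library sizes within each tissue class
  n_by_pool <- vapply(pools, function(p) {
    sel <- cls == p
    if (!any(sel)) return(rep(0L, nrow(mat)))
    as.integer(rowSums(mat[, sel, drop = FALSE]))
  }, integer(nrow(mat)))
  if (nrow(mat) == 1L) n_by_pool <- matrix(n_by_pool, nrow = 1,
                                           dimnames = list(NULL, pools))
  N_by_pool <- vapply(pools, function(p) sum(totals[cls == p]), numeric(1))
  tibble(
    gene_id = rep(genes, times = length(pools)),
    pool    = rep(pools, each = length(genes)),
    n       = as.integer(n_by_pool[cbind(
                rep(seq_along(genes), times = length(pools)),
                rep(seq_along(pools), each = length(genes)))]),
    N       = as.integer(rep(N_by_pool, each = length(genes)))
  )
}

# Shared TSV reader with header validation.
read_tsv_checked <- function(path, required, exact = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path),
          class = "estdigex_error_missing_file")
  }
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (exact) {
    if (!identical(names(df), required)) {
      abort(sprintf("malformed header in %s: expected '%s', found '%s'",
                    path, paste(required, collapse = "\t"),
                    paste(names(df), collapse = "\t")),
            class = "estdigex_error_malformed_header")
    }
  } else if (!all(required %in% names(df)) ||
             names(df)[1] != required[1]) {
    abort(sprintf("malformed header in %s: first column must be '%s'",
                  path, required[1]),
          class = "estdigex_error_malformed_header")
  }
  df
}
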