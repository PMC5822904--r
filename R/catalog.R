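# The inflorescence development-related gene (IDG) catalog: loader for the
# packaged chromosome-distribution table, subgenome presence classes,
# duplication and per-group summary statistics, and the IDG naming scheme.

#' Path to the packaged IDG catalog fixture
#' @return File path of the catalog TSV shipped with the package.
#' @export
idg_catalog_path <- function() {
  system.file("extdata", "idg_catalog.tsv", package = "estdigex",
              mustWork = TRUE)
}

parse_chromosome <- function(chrom) {
  ok <- grepl("^[1-7][ABD]$", chrom)
  if (!all(ok | is.na(chrom))) {
    abort(paste0("malformed chromosome token(s): ",
                 paste(unique(chrom[!ok & !is.na(chrom)]), collapse = ", ")),
          class = "estdigex_error_bad_chromosome")
  }
  tibble(group = as.integer(substr(chrom, 1, 1)),
         subgenome = substr(chrom, 2, 2))
}

#' Load the IDG gene catalog
#'
#' Reads a catalog TSV (`set_id  slot  chrom  copies  code`, one row per
#' subgenome slot of each gene set) and validates it: chromosome tokens must
#' parse to homoeologous group 1-7 plus subgenome A/B/D, present slots need a
#' copy count of at least 1, and a slot carries either copies or an absent
#' code (`a` gene not found, `b` genomic DNA only with no EST support, `c`
#' not inflorescence-predominantly expressed), never both.
#'
#' Two documented corrections are applied to the packaged transcription of
#' the printed table (`fix_known_issues = TRUE`, the default): the two rows
#' `IDG050.1`/`IDG050.2` — the same ancestral set duplicated on 6A and 6D —
#' merge into one set `IDG050` with two copies each on 6A and 6D, and the
#' second occurrence of an `IDG022` row in the group-3 block is relabelled
#' `IDG028` (the printed table lists IDG022 twice and IDG028 never, yet its
#' own set totals require 59 distinct sets). Each correction emits a message.
#'
#' @param path Catalog TSV; defaults to the packaged fixture.
#' @param fix_known_issues Apply the two documented corrections.
#' @return A tibble of class `estdigex_catalog`: `set_id`, `slot`, `chrom`,
#'   `group`, `subgenome`, `copies`, `code`, one row per subgenome slot.
#' @export
#' @examples
#' cat59 <- load_catalog()
#' dplyr::filter(cat59, set_id == "IDG042")
load_catalog <- function(path = idg_catalog_path(), fix_known_issues = TRUE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          set_id = "c", slot = "c", chrom = "c",
                          copies = "i", code = "c"))
  if (!identical(names(df), c("set_id", "slot", "chrom", "copies", "code"))) {
    abort("malformed catalog header",
          class = "estdigex_error_malformed_header")
  }
  present <- !is.na(df$chrom)
  if (any(present & is.na(df$copies)) || any(df$copies[present] < 1)) {
    abort("present slots must carry a copy count >= 1",
          class = "estdigex_error_bad_copy_count")
  }
  if (any(present & !is.na(df$code)) || any(!present & is.na(df$code))) {
    abort("a slot has either copies or an absent code, never both",
          class = "estdigex_error_bad_slot")
  }
  if (!all(df$code[!present] %in% c("a", "b", "c"))) {
    abort("absent codes must be one of a, b, c",
          class = "estdigex_error_bad_slot")
  }

  if (fix_known_issues) {
    # duplicated IDG022 block -> IDG028 (second occurrence, in row order)
    i22 <- which(df$set_id == "IDG022")
    if (length(i22) == 6L) {
      df$set_id[i22[4:6]] <- "IDG028"
      message("catalog correction: second IDG022 row block relabelled IDG028")
    }
    # IDG050.1 + IDG050.2 -> one set, two copies each on 6A and 6D
    i50 <- grepl("^IDG050\\.", df$set_id)
    if (any(i50)) {
      sub <- df[i50, ]
      merged <- sub %>%
        dplyr::group_by(.data$slot) %>%
        dplyr::summarise(
          chrom = if (any(!is.na(.data$chrom))) {
            unique(stats::na.omit(.data$chrom))
          } else NA_character_,
          copies = if (any(!is.na(.data$copies))) {
            sum(.data$copies, na.rm = TRUE)
          } else NA_integer_,
          code = if (all(is.na(.data$chrom))) "b" else NA_character_,
          .groups = "drop") %>%
        dplyr::mutate(set_id = "IDG050") %>%
        dplyr::select("set_id", "slot", "chrom", "copies", "code")
      df <- dplyr::bind_rows(df[seq_len(min(which(i50)) - 1), ], merged,
                             df[setdiff(which(!i50),
                                        seq_len(min(which(i50)) - 1)), ])
      message("catalog correction: IDG050.1/IDG050.2 merged into IDG050")
    }
  }

  pc <- parse_chromosome(df$chrom)
  out <- dplyr::bind_cols(df[, c("set_id", "slot", "chrom")], pc,
                          df[, c("copies", "code")])
  mismatch <- !is.na(out$chrom) & out$subgenome != out$slot
  if (any(mismatch)) {
    abort(paste0("slot/subgenome mismatch for set(s): ",
                 paste(unique(out$set_id[mismatch]), collapse = ", ")),
          class = "estdigex_error_bad_chromosome")
  }
  class(out) <- c("estdigex_catalog", class(out))
  out
}

#' Subgenome presence class of each gene set
#'
#' Number of distinct subgenomes (A, B, D) in which a set has at least one
#' inflorescence-predominant copy: 3 for complete homoeolog triads, 2 or 1
#' where copies were lost, lack EST support, or lost the expression pattern.
#' A set spanning different homoeologous groups (translocation) still counts
#' subgenomes, not groups.
#'
#' @param catalog Catalog tibble from [load_catalog()].
#' @return Tibble `set_id, presence` (presence in 1:3), one row per set, in
#'   catalog order.
#' @export
presence_class <- function(catalog) {
  catalog %>%
    dplyr::group_by(set_id = factor(.data$set_id,
                                    levels = unique(.data$set_id))) %>%
    dplyr::summarise(
      presence = dplyr::n_distinct(.data$subgenome[!is.na(.data$copies) &
                                                     .data$copies >= 1]),
      .groups = "drop") %>%
    dplyr::mutate(set_id = as.character(.data$set_id))
}

# round half up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize the gene catalog
#'
#' Computes the subgenome/duplication statistics of the catalog: total gene
#' copies and nonredundant sets, gene counts and percentages per homoeologous
#' group (percentages of gene copies, rounded half-up to one decimal; group
#' membership is a property of each chromosome token, so translocated sets
#' contribute per chromosome), subgenome presence-class counts, and the sets
#' with intrachromosomal duplications (any slot with more than one copy).
#'
#' @param catalog Catalog tibble from [load_catalog()].
#' @return An object of class `catalog_summary` with elements `total_genes`,
#'   `total_sets`, `per_group` (tibble `group, genes, pct`),
#'   `presence_counts` (named vector for 3/2/1 subgenomes), `dup_sets`,
#'   `dup_sets_group6`. Has `tidy()` and `glance()` methods.
#' @export
#' @examples
#' summarize_catalog(load_catalog())
summarize_catalog <- function(catalog) {
  if (!nrow(catalog)) {
    abort("catalog is empty", class = "estdigex_error_domain")
  }
  present <- catalog[!is.na(catalog$copies), ]
  total_genes <- sum(present$copies)
  total_sets <- dplyr::n_distinct(catalog$set_id)
  per_group <- present %>%
    dplyr::group_by(group = .data$group) %>%
    dplyr::summarise(genes = sum(.data$copies), .groups = "drop") %>%
    tidyr::complete(group = 1:7, fill = list(genes = 0L)) %>%
    dplyr::mutate(pct = round_half_up(100 * .data$genes / total_genes, 1))
  pres <- presence_class(catalog)
  presence_counts <- vapply(c(`3` = 3L, `2` = 2L, `1` = 1L),
                            function(k) sum(pres$presence == k), integer(1))
  dup <- present %>%
    dplyr::filter(.data$copies > 1)
  dup_sets <- unique(dup$set_id)
  dup_sets_group6 <- unique(dup$set_id[dup$group == 6L])
  structure(
    list(total_genes = total_genes, total_sets = total_sets,
         per_group = per_group, presence_counts = presence_counts,
         dup_sets = dup_sets, dup_sets_group6 = dup_sets_group6),
    class = "catalog_summary"
  )
}

#' @export
tidy.catalog_summary <- function(x, ...) x$per_group

#' @export
glance.catalog_summary <- function(x, ...) {
  tibble(
    total_genes = x$total_genes,
    total_sets = x$total_sets,
    pct_groups_1_3_6 = round_half_up(
      100 * sum(x$per_group$genes[x$per_group$group %in% c(1, 3, 6)]) /
        x$total_genes, 1),
    pct_group_4 = x$per_group$pct[x$per_group$group == 4],
    sets_three_subgenomes = unname(x$presence_counts["3"]),
    sets_two_subgenomes = unname(x$presence_counts["2"]),
    sets_one_subgenome = unname(x$presence_counts["1"]),
    n_dup_sets = length(x$dup_sets),
    n_dup_sets_group6 = length(x$dup_sets_group6)
  )
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("IDG catalog: %d genes in %d nonredundant sets\n",
              x$total_genes, x$total_sets))
  cat(sprintf("  subgenome presence 3/2/1: %d/%d/%d sets\n",
              x$presence_counts["3"], x$presence_counts["2"],
              x$presence_counts["1"]))
  cat(sprintf("  duplicated sets: %d (%d on group-6 chromosomes)\n",
              length(x$dup_sets), length(x$dup_sets_group6)))
  print(x$per_group)
  invisible(x)
}

#' Format an IDG gene identifier
#'
#' Identified genes are coded in numerical order with the prefix `IDG` and a
#' zero-padded three-digit set number; homoeologous copies carry the
#' chromosome assignment as a suffix, and multiple copies duplicated on the
#' same chromosome are differentiated by a numerical suffix before it:
#' `IDG{nnn}[.{k}]-{chrom}`.
#'
#' @param set_index Set number, 1-999.
#' @param chromosome Chromosome token such as `"6A"`.
#' @param duplication_index Optional copy number (>= 1) within the
#'   chromosome.
#' @return The formatted identifier string.
#' @export
#' @examples
#' format_gene_id(42, "6A", 3)  # "IDG042.3-6A"
format_gene_id <- function(set_index, chromosome, duplication_index = NULL) {
  stopifnot(set_index >= 1, set_index <= 999)
  parse_chromosome(chromosome)  # validates
  dup <- if (is.null(duplication_index)) "" else {
    stopifnot(duplication_index >= 1)
    paste0(".", duplication_index)
  }
  sprintf("IDG%03d%s-%s", as.integer(set_index), dup, chromosome)
}

#' Expand a catalog into per-copy gene identifiers
#'
#' One row per gene copy, named with [format_gene_id()]; duplicated copies on
#' a chromosome are numbered 1..k. Useful for joining catalog structure to
#' per-gene expression results.
#'
#' @param catalog Catalog tibble from [load_catalog()].
#' @return Tibble `set_id, chrom, group, subgenome, copy, gene_id`.
#' @export
catalog_gene_ids <- function(catalog) {
  present <- catalog[!is.na(catalog$copies), ]
  present %>%
    dplyr::rowwise() %>%
    dplyr::reframe(
      set_id = .data$set_id, chrom = .data$chrom, group = .data$group,
      subgenome = .data$subgenome, copy = seq_len(.data$copies)) %>%
    dplyr::mutate(
      gene_id = mapply(function(s, ch, k, nc) {
        idx <- as.integer(sub("^IDG", "", s))
        format_gene_id(idx, ch, if (nc > 1) k else NULL)
      }, .data$set_id, .data$chrom, .data$copy,
      rep(present$copies, present$copies))
    )
}
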