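# RNA-seq-side statistics: FPKM, relative expression specificity (RES),
# Pearson chi-square differential test, heat-map abundance quotient, and the
# 2^-ddCt fold change.

#' FPKM normalization
#'
#' Fragments per kilobase of transcript model per million mapped reads:
#' `raw_count * 1e9 / (gene_length_bp * mapped_total)`. Linear in the count,
#' inversely proportional to gene length and sequencing depth.
#'
#' @param raw_count Reads mapped to the gene (>= 0). Vectorized.
#' @param gene_length_bp Transcript model length in base pairs (> 0).
#' @param mapped_total Total mapped reads in the sample (> 0).
#' @return FPKM values.
#' @export
#' @examples
#' fpkm(100, 1000, 1e6)  # 100
fpkm <- function(raw_count, gene_length_bp, mapped_total) {
  if (any(gene_length_bp <= 0) || any(mapped_total <= 0)) {
    abort("gene_length_bp and mapped_total must be positive",
          class = "estdigex_error_domain")
  }
  if (any(raw_count < 0)) {
    abort("raw_count must be non-negative",
          class = "estdigex_error_negative_count")
  }
  raw_count * 1e9 / (gene_length_bp * mapped_total)
}

#' Relative expression specificity (RES) of a tissue
#'
#' For a focal tissue A, let B be the tissue in which the gene is most highly
#' expressed among a comparison set excluding A (ties broken by the canonical
#' tissue order, [rnaseq_tissues()]). Then
#' \deqn{RES = (expr_A - expr_B) / expr_A.}
#' RES is at most 1 (equal to 1 exactly when B has zero expression), can be
#' negative when B exceeds A, is undefined when `expr_A = 0`
#' (`defined = FALSE`), and is invariant to rescaling all expression values
#' by a common positive factor. The higher the RES, the more specific the
#' expression in A.
#'
#' @param expr_a Expression (FPKM) in the focal tissue A.
#' @param expr_others Named numeric vector of expression in the comparison
#'   tissues (names from [rnaseq_tissues()]).
#' @return One-row tibble: `tissue_b`, `res`, `defined`.
#' @export
#' @examples
#' res_specificity(10, c(ROOT = 2, LEAF = 5, STEM = 1))
res_specificity <- function(expr_a, expr_others) {
  if (!length(expr_others)) {
    abort("comparison set must be nonempty",
          class = "estdigex_error_empty_comparison")
  }
  ord <- order(match(names(expr_others), rnaseq_tissues()))
  expr_others <- expr_others[ord]
  b <- which.max(expr_others)  # first max in canonical order
  expr_b <- unname(expr_others[b])
  if (expr_a == 0) {
    return(tibble(tissue_b = names(expr_others)[b], res = NA_real_,
                  defined = FALSE))
  }
  tibble(tissue_b = names(expr_others)[b],
         res = (expr_a - expr_b) / expr_a,
         defined = TRUE)
}

#' Pearson chi-square test for an expression difference between two samples
#'
#' Tests whether a gene's read count differs between two samples relative to
#' their sequencing depths, as a Pearson chi-square on the 2x2 table
#' `[[count_a, depth_a - count_a], [count_b, depth_b - count_b]]` with one
#' degree of freedom and (by default) no continuity correction. Raw counts
#' and depths are compared, not length-normalized values — both samples see
#' the same gene, so length cancels. A difference is called significant when
#' `p < alpha` (strict).
#'
#' Degenerate tables in which both proportions are identically 0 or 1 have no
#' evidence of difference and return statistic 0, p 1.
#'
#' @param count_a,count_b Read counts in the two samples.
#' @param depth_a,depth_b Mapped-read totals (> 0).
#' @param alpha Significance level (default 0.05).
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `significant`.
#' @export
#' @examples
#' chi_square_diff(30, 1000, 10, 1000)
chi_square_diff <- function(count_a, depth_a, count_b, depth_b,
                            alpha = 0.05, correct = FALSE) {
  if (depth_a <= 0 || depth_b <= 0) {
    abort("depths must be positive", class = "estdigex_error_domain")
  }
  if (count_a > depth_a || count_b > depth_b || count_a < 0 || count_b < 0) {
    abort("require 0 <= count <= depth", class = "estdigex_error_domain")
  }
  tot <- count_a + count_b
  if (tot == 0 || tot == depth_a + depth_b) {
    return(tibble(statistic = 0, df = 1L, p_value = 1, significant = FALSE))
  }
  tab <- matrix(c(count_a, depth_a - count_a,
                  count_b, depth_b - count_b), nrow = 2, byrow = TRUE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  tibble(statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value),
         significant = unname(ht$p.value) < alpha)
}

#' 2^-ddCt relative expression fold change
#'
#' Converts a delta-delta cycle-threshold value from comparative qPCR into a
#' fold change: `2^(-ddct)`. A ddCt of 0 is no change; each unit decrease
#' doubles the relative expression.
#'
#' @param delta_delta_ct Numeric ddCt values.
#' @return Fold changes `2^(-ddct)`.
#' @export
#' @examples
#' ddct_fold_change(c(0, -1, 1))
ddct_fold_change <- function(delta_delta_ct) {
  2^(-delta_delta_ct)
}

#' Per-tissue expression values with max-over-stages collapsing
#'
#' Collapses a long expression table to one row per gene and tissue, keeping
#' the developmental stage with the maximal FPKM (ties broken by stage order
#' of appearance). The maximizing stage's raw count and mapped total are kept
#' alongside, so significance tests are run on the same sample that supplied
#' the expression value.
#'
#' @param expression Expression tibble from [read_expression_table()] /
#'   [validate_expression_table()].
#' @return Tibble: `gene_id, tissue, stage, raw_count, mapped_total, fpkm`.
#' @export
tissue_stage_max <- function(expression) {
  expression %>%
    dplyr::group_by(.data$gene_id, .data$tissue) %>%
    dplyr::slice(which.max(.data$fpkm)) %>%
    dplyr::ungroup() %>%
    dplyr::select("gene_id", "tissue", "stage", "raw_count",
                  "mapped_total", "fpkm")
}

#' RES and chi-square profile of every gene for a focal tissue
#'
#' For each gene: collapse stages by maximal FPKM, compute RES of the focal
#' tissue against all other tissues, and test the focal-vs-B count difference
#' with [chi_square_diff()]. Genes lacking the focal tissue are skipped.
#'
#' @param expression Long expression tibble.
#' @param focal Focal tissue A (one of [rnaseq_tissues()]).
#' @param alpha Significance level for the chi-square call.
#' @return Tibble of class `estdigex_profile`: `gene_id, tissue_a, tissue_b,
#'   res, defined, chi2, p, significant`.
#' @export
profile_expression <- function(expression, focal = "STAMEN", alpha = 0.05) {
  focal <- match.arg(focal, rnaseq_tissues())
  collapsed <- tissue_stage_max(expression)
  per_gene <- split(collapsed, collapsed$gene_id)
  rows <- purrr::map(per_gene, function(g) {
    a <- g[g$tissue == focal, ]
    if (!nrow(a)) return(NULL)
    others <- g[g$tissue != focal, ]
    if (!nrow(others)) return(NULL)
    r <- res_specificity(a$fpkm, stats::setNames(others$fpkm, others$tissue))
    b <- others[others$tissue == r$tissue_b, ]
    ct <- chi_square_diff(a$raw_count, a$mapped_total,
                          b$raw_count, b$mapped_total, alpha = alpha)
    tibble(gene_id = g$gene_id[1], tissue_a = focal, tissue_b = r$tissue_b,
           res = r$res, defined = r$defined, chi2 = ct$statistic,
           p = ct$p_value, significant = ct$significant)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("estdigex_profile", class(out))
  out
}

#' Heat-map relative abundance quotients
#'
#' For each gene and tissue, divides the tissue's FPKM (maximal over stages
#' when several are profiled) by the mean of those per-tissue FPKM values
#' over all genes, then log-transforms: `log2(quotient + eps)`. The
#' pseudocount `eps` keeps zero-expression cells finite.
#'
#' @param expression Long expression tibble.
#' @param eps Pseudocount added before the log (default 0.01).
#' @param base Logarithm base (default 2).
#' @return Tibble of class `estdigex_abundance`: `gene_id, tissue, fpkm,
#'   quotient, log_quotient`.
#' @export
relative_abundance <- function(expression, eps = 0.01, base = 2) {
  collapsed <- tissue_stage_max(expression)
  gene_set_mean <- mean(collapsed$fpkm)
  if (!is.finite(gene_set_mean) || gene_set_mean <= 0) {
    abort("gene-set mean FPKM must be positive",
          class = "estdigex_error_domain")
  }
  out <- collapsed %>%
    dplyr::mutate(quotient = .data$fpkm / gene_set_mean,
                  log_quotient = log(.data$quotient + eps, base = base)) %>%
    dplyr::select("gene_id", "tissue", "fpkm", "quotient", "log_quotient")
  attr(out, "gene_set_mean") <- gene_set_mean
  class(out) <- c("estdigex_abundance", class(out))
  out
}

#' Write an expression profile to TSV
#'
#' Stable column order: `gene_id  tissue_a  tissue_b  res  defined  chi2  p
#' significant`.
#'
#' @param profile An `estdigex_profile` tibble.
#' @param path Output file.
#' @export
write_profile <- function(profile, path) {
  cols <- c("gene_id", "tissue_a", "tissue_b", "res", "defined",
            "chi2", "p", "significant")
  readr::write_tsv(as_tibble(profile)[cols], path)
  invisible(path)
}
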