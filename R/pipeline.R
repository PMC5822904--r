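# Orchestration: two-tier screen -> RNA-seq support filter -> RES/chi-square
# profiling -> group classification -> catalog summary, with TSV/JSON
# reporting.

#' RNA-seq support filter for screen candidates
#'
#' A screened gene is retained when the RNA-seq data corroborate floral
#' enrichment: its inflorescence (any profiled stage), stamen, or pistil
#' expression is significantly more abundant (chi-square at `alpha`,
#' direction included) than in every vegetative tissue. Genes with no
#' expression rows at all cannot be tested and are retained with a
#' `no_rnaseq_data` flag rather than dropped; genes failing the test are
#' listed as disregarded with the reason.
#'
#' @param genes Character vector of screened gene ids (typically the passing
#'   genes of [run_screen()]).
#' @param expression Long expression tibble.
#' @param alpha Significance level (default 0.05).
#' @return A list: `retained` (tibble `gene_id, support, no_rnaseq_data`),
#'   `disregarded` (tibble `gene_id, reason`).
#' @export
rnaseq_support_filter <- function(genes, expression, alpha = 0.05) {
  collapsed <- tissue_stage_max(expression)
  raw <- expression  # inflorescence: any stage may supply support
  veg <- vegetative_tissues()
  support_for <- function(g) {
    rows <- collapsed[collapsed$gene_id == g, ]
    if (!nrow(rows)) return("no_rnaseq_data")
    veg_rows <- rows[rows$tissue %in% veg, ]
    beats_all_veg <- function(a) {
      nrow(veg_rows) > 0 &&
        all(vapply(seq_len(nrow(veg_rows)), function(i) {
          sig_higher(a, veg_rows[i, ], alpha)
        }, logical(1)))
    }
    # stamen / pistil at their max stage
    for (t in c("STAMEN", "PISTIL")) {
      a <- rows[rows$tissue == t, ]
      if (nrow(a) && beats_all_veg(a)) return(tolower(t))
    }
    # inflorescence: any profiled stage qualifies
    infl <- raw[raw$gene_id == g & raw$tissue == "INFLORESCENCE", ]
    for (i in seq_len(nrow(infl))) {
      if (beats_all_veg(infl[i, ])) return("inflorescence")
    }
    "none"
  }
  support <- unname(vapply(genes, support_for, character(1)))
  retained <- tibble(
    gene_id = genes[support != "none"],
    support = support[support != "none"],
    no_rnaseq_data = support[support != "none"] == "no_rnaseq_data"
  )
  disregarded <- tibble(
    gene_id = genes[support == "none"],
    reason = "not_more_abundant_in_inflorescence_stamen_or_pistil"
  )
  list(retained = retained, disregarded = disregarded)
}

#' Run the full comparative-transcriptomics pipeline
#'
#' Composes the stages on count-matrix inputs: tier-1 screen of the contig
#' count matrix, tier-2 confirmation screen of the coding-sequence matrix
#' restricted to tier-1 passers, RNA-seq support filter, RES/chi-square
#' profiling of the focal tissues, expression-group classification, and
#' (optionally) the catalog summary. Deterministic given inputs and
#' parameters. When `out_dir` is given, per-stage TSVs and a JSON run summary
#' (stage funnel counts plus every parameter value) are written there.
#'
#' @param tier1,tier2 [est_count_matrix()]s at tiers `contig_90` and
#'   `cds_99`. `tier2` may be `NULL` to screen at tier 1 only.
#' @param libraries Library metadata table.
#' @param expression Long expression tibble (`NULL` skips the RNA-seq
#'   stages).
#' @param threshold_tier1,threshold_tier2 Sampling-probability thresholds
#'   (defaults 1e-4 and 0.01).
#' @param alpha Chi-square significance level (default 0.05).
#' @param negligible_fpkm Classifier FPKM floor (default 0.5).
#' @param tail_sum,merged_pool,direction_guard Screen options, see
#'   [run_screen()].
#' @param catalog Optional catalog tibble to summarize alongside.
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return A list of class `estdigex_run`: per-stage results (`screen_tier1`,
#'   `screen_tier2`, `support`, `profiles`, `groups`, `catalog_summary`) and
#'   `funnel` (tibble `stage, n`).
#' @export
run_pipeline <- function(tier1, libraries, tier2 = NULL, expression = NULL,
                         threshold_tier1 = 1e-4, threshold_tier2 = 0.01,
                         alpha = 0.05, negligible_fpkm = 0.5,
                         tail_sum = FALSE, merged_pool = FALSE,
                         direction_guard = TRUE, catalog = NULL,
                         out_dir = NULL) {
  libs <- filter_libraries(libraries)
  s1 <- run_screen(tier1, libs, threshold = threshold_tier1,
                   tail_sum = tail_sum, merged_pool = merged_pool,
                   direction_guard = direction_guard, prefiltered = TRUE)
  pass1 <- s1$gene_id[s1$passes]

  s2 <- NULL
  candidates <- pass1
  if (!is.null(tier2)) {
    sub2 <- tier2[tier2$gene_id %in% pass1, , drop = FALSE]
    s2 <- run_screen(sub2, libs, threshold = threshold_tier2,
                     tail_sum = tail_sum, merged_pool = merged_pool,
                     direction_guard = direction_guard, prefiltered = TRUE)
    candidates <- s2$gene_id[s2$passes]
  }

  support <- NULL
  profiles <- NULL
  groups <- NULL
  retained <- candidates
  if (!is.null(expression)) {
    support <- rnaseq_support_filter(candidates, expression, alpha = alpha)
    retained <- support$retained$gene_id
    expr_ret <- expression[expression$gene_id %in% retained, ]
    if (nrow(expr_ret)) {
      profiles <- dplyr::bind_rows(
        profile_expression(expr_ret, focal = "STAMEN", alpha = alpha),
        profile_expression(expr_ret, focal = "PISTIL", alpha = alpha),
        profile_expression(expr_ret, focal = "INFLORESCENCE", alpha = alpha)
      )
      groups <- classify_genes(expr_ret, negligible_fpkm = negligible_fpkm,
                               alpha = alpha)
    }
  }

  cat_sum <- if (!is.null(catalog)) summarize_catalog(catalog) else NULL

  funnel <- tibble(
    stage = c("input_genes", "tier1_pass", "tier2_pass", "rnaseq_supported",
              "classified"),
    n = c(nrow(tier1), length(pass1), length(candidates), length(retained),
          if (is.null(groups)) length(retained) else nrow(groups))
  )

  run <- structure(
    list(screen_tier1 = s1, screen_tier2 = s2, support = support,
         profiles = profiles, groups = groups, catalog_summary = cat_sum,
         funnel = funnel,
         params = list(threshold_tier1 = threshold_tier1,
                       threshold_tier2 = threshold_tier2, alpha = alpha,
                       negligible_fpkm = negligible_fpkm,
                       tail_sum = tail_sum, merged_pool = merged_pool,
                       direction_guard = direction_guard)),
    class = "estdigex_run")

  if (!is.null(out_dir)) write_run_report(run, out_dir)
  run
}

#' Write the per-stage TSVs and JSON summary of a pipeline run
#'
#' @param run An `estdigex_run` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_screen_records(run$screen_tier1, p("screen_tier1.tsv"))
  if (!is.null(run$screen_tier2)) {
    write_screen_records(run$screen_tier2, p("screen_tier2.tsv"))
  }
  if (!is.null(run$support)) {
    readr::write_tsv(run$support$retained, p("supported_genes.tsv"))
    readr::write_tsv(run$support$disregarded, p("disregarded_genes.tsv"))
  }
  if (!is.null(run$profiles)) write_profile(run$profiles, p("profiles.tsv"))
  if (!is.null(run$groups)) {
    write_group_assignments(run$groups, p("groups.tsv"))
  }
  readr::write_tsv(run$funnel, p("funnel.tsv"))
  summary <- list(
    funnel = stats::setNames(as.list(run$funnel$n), run$funnel$stage),
    params = run$params,
    groups = if (!is.null(run$groups)) {
      as.list(table(run$groups$group))
    } else NULL,
    catalog = if (!is.null(run$catalog_summary)) {
      as.list(glance(run$catalog_summary))
    } else NULL
  )
  jsonlite::write_json(summary, p("run_summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.estdigex_run <- function(x, ...) {
  cat("estdigex pipeline run\n")
  print(x$funnel)
  invisible(x)
}

#' @export
glance.estdigex_run <- function(x, ...) {
  tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
}
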