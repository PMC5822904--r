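# Expression-group taxonomy: a deterministic decision procedure assigning
# each gene to one of six subgroups (or UNCLASSIFIED / LOW_DATA) from its
# FPKM profile and pairwise chi-square significance calls.

group_levels <- function() {
  c("G1_1", "G1_2", "G2_1", "G2_2", "G3_1", "G3_2",
    "UNCLASSIFIED", "LOW_DATA")
}

# Is tissue a's expression significantly higher than tissue b's?
# Proportion test on raw counts vs depths; "higher" is directional.
sig_higher <- function(a, b, alpha) {
  if (a$raw_count / a$mapped_total <= b$raw_count / b$mapped_total) {
    return(FALSE)
  }
  chi_square_diff(a$raw_count, a$mapped_total,
                  b$raw_count, b$mapped_total, alpha = alpha)$significant
}

#' Classify one gene into an expression group
#'
#' Assigns a gene to one of six expression subgroups from its per-tissue FPKM
#' values (stage-collapsed by maximal FPKM) and pairwise chi-square
#' significance calls against the four vegetative tissues (root, leaf, stem,
#' grain). The groups describe where expression concentrates:
#' \describe{
#'   \item{G3 (stamen-specific)}{negligible FPKM in every vegetative tissue,
#'     stamen expressed and significantly higher than each vegetative tissue.
#'     G3_1: inflorescence also negligible; G3_2: inflorescence significantly
#'     higher than each vegetative tissue as well.}
#'   \item{G2 (floral-organ-enriched over a vegetative baseline)}{expressed
#'     in at least one vegetative tissue, with stamen and/or pistil
#'     significantly higher than every vegetative tissue. G2_1: the pistil
#'     condition holds; G2_2: it does not (pistil not different from, or
#'     lower than, at least one vegetative tissue).}
#'   \item{G1 (inflorescence-predominant)}{inflorescence significantly higher
#'     than each vegetative tissue. G1_2: stamen, pistil and all vegetative
#'     FPKM negligible; G1_1 otherwise.}
#'   \item{LOW_DATA}{every tissue below the negligible-FPKM floor — too few
#'     reads to classify.}
#'   \item{UNCLASSIFIED}{no clause fires.}
#' }
#' Precedence G3 > G2 > G1 resolves overlaps deterministically; the returned
#' evidence records every clause evaluated so assignments are auditable.
#' "Inflorescence" expression is the maximum over its profiled stages,
#' consistent with the heat-map max-over-stages rule.
#'
#' @param gene_tbl Stage-collapsed rows for one gene ([tissue_stage_max()]
#'   output) covering all of [rnaseq_tissues()].
#' @param negligible_fpkm FPKM floor below which expression is treated as
#'   negligible (default 0.5).
#' @param alpha Significance level for chi-square calls (default 0.05).
#' @return One-row tibble: `gene_id`, `group`, `evidence` (named logical
#'   list-column).
#' @export
classify_gene <- function(gene_tbl, negligible_fpkm = 0.5, alpha = 0.05) {
  missing <- setdiff(rnaseq_tissues(), gene_tbl$tissue)
  if (length(missing)) {
    abort(sprintf("incomplete profile for gene '%s': missing %s",
                  gene_tbl$gene_id[1], paste(missing, collapse = ", ")),
          class = "estdigex_error_incomplete_profile")
  }
  row_of <- function(t) gene_tbl[gene_tbl$tissue == t, ]
  fpkm_of <- function(t) row_of(t)$fpkm
  veg <- vegetative_tissues()
  sig_vs_all_veg <- function(t) {
    all(vapply(veg, function(v) sig_higher(row_of(t), row_of(v), alpha),
               logical(1)))
  }

  ev <- list(
    all_low          = all(gene_tbl$fpkm < negligible_fpkm),
    veg_all_neg      = all(vapply(veg, fpkm_of, numeric(1)) <
                             negligible_fpkm),
    veg_any_expr     = any(vapply(veg, fpkm_of, numeric(1)) >=
                             negligible_fpkm),
    stamen_expr      = fpkm_of("STAMEN") >= negligible_fpkm,
    stamen_sig_veg   = sig_vs_all_veg("STAMEN"),
    pistil_sig_veg   = sig_vs_all_veg("PISTIL"),
    inflo_sig_veg    = sig_vs_all_veg("INFLORESCENCE"),
    inflo_neg        = fpkm_of("INFLORESCENCE") < negligible_fpkm,
    stamen_neg       = fpkm_of("STAMEN") < negligible_fpkm,
    pistil_neg       = fpkm_of("PISTIL") < negligible_fpkm
  )

  group <- if (ev$all_low) {
    "LOW_DATA"
  } else if (ev$veg_all_neg && ev$stamen_expr && ev$stamen_sig_veg &&
             (ev$inflo_neg || ev$inflo_sig_veg)) {
    if (ev$inflo_neg) "G3_1" else "G3_2"
  } else if (ev$veg_any_expr && (ev$stamen_sig_veg || ev$pistil_sig_veg)) {
    if (ev$pistil_sig_veg) "G2_1" else "G2_2"
  } else if (ev$inflo_sig_veg) {
    if (ev$stamen_neg && ev$pistil_neg && ev$veg_all_neg) "G1_2" else "G1_1"
  } else {
    "UNCLASSIFIED"
  }

  tibble(gene_id = gene_tbl$gene_id[1], group = group, evidence = list(ev))
}

#' Classify every gene in an expression table
#'
#' Runs [classify_gene()] on each gene, recomputes RES of stamen, pistil and
#' inflorescence for reporting (RES is descriptive here, never a
#' classification criterion), and attaches a per-group count summary.
#' Classification is a pure function of the profiles and parameters:
#' permuting gene order permutes rows but changes no assignment.
#'
#' @param expression Long expression tibble covering the canonical tissues.
#' @param negligible_fpkm,alpha See [classify_gene()].
#' @return A tibble of class `estdigex_groups`: `gene_id`, `group`,
#'   `res_stamen`, `res_pistil`, `res_inflorescence`, `evidence`
#'   (list-column), `evidence_json`. `glance()` returns the group counts.
#' @export
classify_genes <- function(expression, negligible_fpkm = 0.5, alpha = 0.05) {
  collapsed <- tissue_stage_max(expression)
  res_for <- function(focal) {
    p <- profile_expression(expression, focal = focal, alpha = alpha)
    stats::setNames(p$res, p$gene_id)
  }
  res_sta <- res_for("STAMEN")
  res_pis <- res_for("PISTIL")
  res_inf <- res_for("INFLORESCENCE")
  out <- collapsed %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::group_modify(~ classify_gene(.x %>%
                                          dplyr::mutate(gene_id = .y$gene_id),
                                        negligible_fpkm = negligible_fpkm,
                                        alpha = alpha)[-1]) %>%
    dplyr::ungroup()
  out <- out[match(unique(expression$gene_id), out$gene_id), ]
  out$res_stamen <- unname(res_sta[out$gene_id])
  out$res_pistil <- unname(res_pis[out$gene_id])
  out$res_inflorescence <- unname(res_inf[out$gene_id])
  out$evidence_json <- vapply(out$evidence, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE))
  }, character(1))
  out <- out[, c("gene_id", "group", "res_stamen", "res_pistil",
                 "res_inflorescence", "evidence", "evidence_json")]
  attr(out, "negligible_fpkm") <- negligible_fpkm
  attr(out, "alpha") <- alpha
  class(out) <- c("estdigex_groups", class(out))
  out
}

#' @export
glance.estdigex_groups <- function(x, ...) {
  counts <- table(factor(x$group, levels = group_levels()))
  dplyr::bind_cols(
    tibble(n_genes = nrow(x)),
    as_tibble(as.list(counts)),
    tibble(negligible_fpkm = attr(x, "negligible_fpkm"),
           alpha = attr(x, "alpha"))
  )
}

#' Write group assignments to TSV
#'
#' Stable column order: `gene_id  group  res_stamen  res_pistil
#' res_inflorescence  evidence_json`.
#'
#' @param groups An `estdigex_groups` tibble.
#' @param path Output file.
#' @export
write_group_assignments <- function(groups, path) {
  cols <- c("gene_id", "group", "res_stamen", "res_pistil",
            "res_inflorescence", "evidence_json")
  readr::write_tsv(as_tibble(groups)[cols], path)
  invisible(path)
}
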