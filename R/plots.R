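# ggplot2 views of the result types.

#' Plot a screen result
#'
#' Inflorescence-pool EST frequency against the smallest per-pool sampling
#' probability, one point per gene, colored by screening route. Genes whose
#' matched ESTs come solely from inflorescence libraries have no finite
#' probability and are drawn at the plot floor.
#'
#' @param object An `estdigex_screen` tibble from [run_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.estdigex_screen <- function(object, ...) {
  pcols <- grep("^P_", names(object), value = TRUE)
  pm <- as.matrix(as_tibble(object)[pcols])
  min_p <- suppressWarnings(apply(pm, 1, min, na.rm = TRUE))
  floor_p <- 10^(floor(log10(min(min_p[is.finite(min_p) & min_p > 0],
                                 1e-12))) - 1)
  df <- tibble(
    f = object$f,
    min_p = pmax(ifelse(is.finite(min_p), min_p, floor_p), floor_p),
    route = object$route
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f, y = .data$min_p,
                                   colour = .data$route)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_x_log10() +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::labs(x = "inflorescence-pool EST frequency f",
                  y = "min sampling probability across pools",
                  colour = "route")
}

#' Plot expression-group counts
#'
#' Bar chart of genes per expression subgroup.
#'
#' @param object An `estdigex_groups` tibble from [classify_genes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.estdigex_groups <- function(object, ...) {
  df <- tibble(group = factor(object$group, levels = group_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "expression group", y = "genes")
}

#' Heat map of relative expression abundance
#'
#' Tile map of the log-transformed abundance quotients from
#' [relative_abundance()]: genes by tissues, fill = log quotient.
#'
#' @param object An `estdigex_abundance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.estdigex_abundance <- function(object, ...) {
  df <- as_tibble(object)
  df$tissue <- factor(df$tissue, levels = rnaseq_tissues())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$gene_id,
                                   fill = .data$log_quotient)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 quotient")
}

#' Plot a catalog summary
#'
#' Gene copies per homoeologous chromosome group.
#'
#' @param object A `catalog_summary` from [summarize_catalog()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.catalog_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_group,
                  ggplot2::aes(x = factor(.data$group), y = .data$genes)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "homoeologous group", y = "gene copies")
}
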