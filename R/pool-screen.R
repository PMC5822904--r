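# The digital differential-expression screen: binomial sampling probability
# and the two-tier decision rules.

#' EST frequency of a gene in the inflorescence pool
#'
#' The frequency `f = m/M`: matched ESTs over total ESTs across the retained
#' inflorescence libraries. This is the success probability plugged into the
#' sampling-probability statistic for the other pools.
#'
#' @param m Matched ESTs in the pool (0 <= m <= M).
#' @param M Total ESTs in the pool (> 0).
#' @return `m/M` as a double.
#' @export
#' @examples
#' pool_est_frequency(10, 100000)
pool_est_frequency <- function(m, M) {
  if (any(M == 0)) {
    abort("EST frequency is undefined for an empty pool (M = 0)",
          class = "estdigex_error_undefined_frequency")
  }
  if (any(m < 0) || any(m > M)) {
    abort("require 0 <= m <= M", class = "estdigex_error_domain")
  }
  m / M
}

#' Binomial sampling probability of an EST count
#'
#' The probability of drawing exactly `n` matched ESTs in `N` trials when the
#' per-EST match probability is `f`, i.e. the binomial point probability
#' \deqn{P = \binom{N}{n} f^n (1-f)^{N-n}.}
#' With `f` estimated from the inflorescence pool, a small `P` for a
#' non-inflorescence pool indicates that the observed count there is
#' improbable under the inflorescence expression level — the digital
#' differential-expression signal. Computed in log space (log-gamma for the
#' binomial coefficient) and exponentiated, so it is stable for pool sizes in
#' the tens of thousands. Edge conventions: `f = 0` gives 1 if `n = 0` else
#' 0; `f = 1` gives 1 if `n = N` else 0.
#'
#' `tail_sum = TRUE` returns the lower-tail sum \eqn{\sum_{k \le n} P(k)}
#' instead, for sensitivity analysis; the point probability is the default
#' statistic.
#'
#' @param n Observed matched ESTs (0 <= n <= N). Vectorized.
#' @param N Pool size.
#' @param f Match probability in [0, 1].
#' @param tail_sum Return the cumulative lower tail instead of the point
#'   probability.
#' @param log Return the log probability (avoids underflow for extreme
#'   tails).
#' @return Probability in [0, 1] (or its log), same length as the inputs.
#' @export
#' @examples
#' sampling_probability(2, 10, 0.1)   # 45 * 0.01 * 0.9^8
sampling_probability <- function(n, N, f, tail_sum = FALSE, log = FALSE) {
  k <- max(length(n), length(N), length(f))
  n <- rep_len(as.numeric(n), k)
  N <- rep_len(as.numeric(N), k)
  f <- rep_len(as.numeric(f), k)
  if (any(n < 0) || any(n > N) || any(f < 0) || any(f > 1)) {
    abort("require 0 <= n <= N and 0 <= f <= 1",
          class = "estdigex_error_domain")
  }
  if (tail_sum) {
    return(stats::pbinom(n, N, f, log.p = log))
  }
  lp <- numeric(k)
  at0 <- f == 0
  at1 <- f == 1
  lp[at0] <- ifelse(n[at0] == 0, 0, -Inf)
  lp[at1] <- ifelse(n[at1] == N[at1], 0, -Inf)
  mid <- !at0 & !at1
  if (any(mid)) {
    lp[mid] <- lchoose(N[mid], n[mid]) + n[mid] * base::log(f[mid]) +
      (N[mid] - n[mid]) * log1p(-f[mid])
  }
  if (log) lp else exp(lp)
}

#' Screen one gene's pooled counts for inflorescence-predominant expression
#'
#' Decision rule, per gene: estimate `f` from the inflorescence pool; for each
#' non-inflorescence pool with `N > 0` compute the sampling probability of its
#' matched count under `f`. The gene passes by route
#' \describe{
#'   \item{SOLE}{matched ESTs come solely from inflorescence libraries
#'     (`m > 0`, every other pool `n = 0`) — threshold-independent.}
#'   \item{SIGNIFICANT}{`m > 0` and every non-empty pool either has `n = 0`
#'     or a sampling probability at or below `threshold` (and, with the
#'     default directionality guard, an observed frequency `n/N` below `f`).}
#'   \item{FAIL}{otherwise (in particular whenever `m = 0`).}
#' }
#' Empty pools (`N = 0`) never block a pass. The condition must hold against
#' each pool separately; `merged_pool = TRUE` instead tests a single merged
#' non-inflorescence pool (sensitivity option).
#'
#' @param pools A tibble `pool, n, N` for one gene ([pool_counts()] rows);
#'   the `INFLORESCENCE` row holds `m`, `M`.
#' @param threshold Significance threshold on the sampling probability.
#' @param tail_sum,merged_pool,direction_guard See [run_screen()].
#' @return One-row tibble: `m`, `M`, `f`, one `P_<pool>` column per
#'   non-inflorescence tissue class, `sole`, `route`, `passes`.
#' @export
screen_gene <- function(pools, threshold, tail_sum = FALSE,
                        merged_pool = FALSE, direction_guard = TRUE) {
  stopifnot(threshold > 0, threshold < 1)
  infl <- pools[pools$pool == "INFLORESCENCE", ]
  other <- pools[pools$pool != "INFLORESCENCE", ]
  m <- infl$n
  M <- infl$N
  f <- pool_est_frequency(m, M)
  if (merged_pool) {
    other <- tibble(pool = "MERGED", n = sum(other$n), N = sum(other$N))
  }
  nonempty <- other$N > 0
  P <- rep(NA_real_, nrow(other))
  P[nonempty] <- sampling_probability(other$n[nonempty], other$N[nonempty],
                                      f, tail_sum = tail_sum)
  sole <- m > 0 && all(other$n == 0)
  pool_ok <- other$n == 0 | !nonempty |
    (P <= threshold &
       (!direction_guard | other$n / pmax(other$N, 1) < f))
  pool_ok[is.na(pool_ok)] <- TRUE  # empty pools: no evidence against
  route <- if (sole) {
    "SOLE"
  } else if (m > 0 && all(pool_ok)) {
    "SIGNIFICANT"
  } else {
    "FAIL"
  }
  out <- tibble(m = m, M = M, f = f, sole = sole, route = route,
                passes = route != "FAIL")
  pcols <- stats::setNames(as.list(P), paste0("P_", tolower(other$pool)))
  dplyr::bind_cols(out[, c("m", "M", "f")], as_tibble(pcols),
                   out[, c("sole", "route", "passes")])
}

#' Default sampling-probability thresholds by homology tier
#'
#' The first-pass screen on contig matches uses 0.0001; the confirmation
#' screen on coding-sequence matches at the stricter homology cutoff uses
#' 0.01.
#'
#' @param tier `"contig_90"` or `"cds_99"`.
#' @return A single threshold.
#' @export
default_threshold <- function(tier = c("contig_90", "cds_99")) {
  switch(match.arg(tier), contig_90 = 1e-4, cds_99 = 0.01)
}

#' Run the digital differential-expression screen on a count matrix
#'
#' Applies [screen_gene()] to every gene of an EST count matrix after pooling
#' counts over the retained libraries of each tissue class. The result is one
#' record per gene, in matrix order, and is fully deterministic. No
#' multiple-testing correction is applied; the number of genes tested is
#' attached as attribute `n_tested` so users can adjust post hoc.
#'
#' @param matrix An [est_count_matrix()].
#' @param libraries Library metadata; filtered with [filter_libraries()]
#'   unless `prefiltered = TRUE`.
#' @param threshold Sampling-probability threshold; defaults to the tier's
#'   value ([default_threshold()]).
#' @param tail_sum Use the cumulative lower tail instead of the point
#'   probability (default `FALSE`).
#' @param merged_pool Test one merged non-inflorescence pool instead of each
#'   pool separately (default `FALSE`).
#' @param direction_guard Require the observed pool frequency `n/N` to lie
#'   below `f` for a significant call (default `TRUE`).
#' @param prefiltered Set `TRUE` if `libraries` has already been filtered.
#' @return A tibble of class `estdigex_screen`: `gene_id`, `tier`, `m`, `M`,
#'   `f`, `P_root`, `P_stem`, `P_leaf`, `P_seed`, `sole`, `route`, `passes`.
#' @export
run_screen <- function(matrix, libraries, threshold = NULL,
                       tail_sum = FALSE, merged_pool = FALSE,
                       direction_guard = TRUE, prefiltered = FALSE) {
  tier <- matrix_tier(matrix)
  if (is.null(threshold)) threshold <- default_threshold(tier)
  stopifnot(threshold > 0, threshold < 1)
  libs <- if (prefiltered) libraries else filter_libraries(libraries)
  keep <- names(matrix)[-1] %in% libs$library_id
  matrix <- matrix[, c(TRUE, keep), drop = FALSE]
  pooled <- pool_counts(matrix, libs)
  recs <- pooled %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::group_modify(~ screen_gene(.x, threshold = threshold,
                                      tail_sum = tail_sum,
                                      merged_pool = merged_pool,
                                      direction_guard = direction_guard)) %>%
    dplyr::ungroup()
  recs <- recs[match(matrix$gene_id, recs$gene_id), ]
  out <- dplyr::bind_cols(tibble(gene_id = matrix$gene_id, tier = tier),
                          recs[, -1])
  attr(out, "n_tested") <- nrow(out)
  attr(out, "threshold") <- threshold
  class(out) <- c("estdigex_screen", class(out))
  out
}

#' Write screen records to TSV
#'
#' Stable column order: `gene_id  tier  f  P_root  P_stem  P_leaf  P_seed
#' sole  route  passes`.
#'
#' @param records An `estdigex_screen` tibble.
#' @param path Output file.
#' @export
write_screen_records <- function(records, path) {
  cols <- c("gene_id", "tier", "f",
            intersect(c("P_root", "P_stem", "P_leaf", "P_seed", "P_merged"),
                      names(records)),
            "sole", "route", "passes")
  readr::write_tsv(as_tibble(records)[cols], path)
  invisible(path)
}

#' @export
glance.estdigex_screen <- function(x, ...) {
  tibble(
    n_tested   = nrow(x),
    n_pass     = sum(x$passes),
    n_sole     = sum(x$route == "SOLE"),
    n_signif   = sum(x$route == "SIGNIFICANT"),
    n_fail     = sum(x$route == "FAIL"),
    threshold  = attr(x, "threshold"),
    tier       = if (nrow(x)) x$tier[1] else NA_character_
  )
}
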