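# Seeded synthetic data with ground-truth labels: multinomial EST libraries
# drawn from tissue-specific transcript-frequency profiles, and Poisson
# RNA-seq counts from designed FPKM profiles.

#' Design a synthetic EST universe
#'
#' Builds tissue-specific transcript-frequency profiles with implanted
#' inflorescence-enriched genes, plus a library sampling plan. Each tissue's
#' profile is a probability vector over genes; implanted genes have an
#' inflorescence:other frequency ratio equal to `fold_enrichment` by
#' construction (`SOLE_INFLO` genes have frequency exactly 0 outside the
#' inflorescence), and the remaining probability mass is spread uniformly
#' over the `NULL`-labelled genes, so a null universe (no implants) has
#' identical frequencies in every tissue.
#'
#' The defaults describe the study conditions the screen is calibrated
#' against: 200 genes of which 20 are implanted (half sole-inflorescence,
#' half predominant) at 100-fold enrichment over a baseline frequency of
#' 1e-5, an inflorescence pool of 100,000 ESTs over five libraries
#' (expected matched count m = 100 for an implanted gene) and four
#' non-inflorescence pools of at least 30,000 ESTs each. The
#' point-probability statistic needs the expected matched count `f * N` in
#' every tested pool to clear roughly 16 with margin (below that, even an
#' observed count far under expectation has point probability above 1e-4),
#' which these sizes give; see the methods vignette for the derivation.
#'
#' @param n_genes Number of genes.
#' @param n_sole,n_predominant Numbers of implanted sole-inflorescence and
#'   inflorescence-predominant genes.
#' @param baseline_freq Per-gene transcript frequency of an implanted gene
#'   outside the inflorescence (and of a predominant gene's background).
#' @param fold_enrichment Inflorescence frequency of implanted genes relative
#'   to `baseline_freq` (> 1).
#' @param library_plan Tibble `tissue_class, est_total`, one row per library.
#' @param tier2_retention Probability that a tier-1 matched EST is retained
#'   in the stricter-homology tier-2 matrix (default 1: tiers identical).
#' @param seed Integer seed; all randomness in the generators derives from
#'   it.
#' @return A list of class `est_design`.
#' @export
est_design <- function(n_genes = 200, n_sole = 10, n_predominant = 10,
                       baseline_freq = 1e-5, fold_enrichment = 100,
                       library_plan = default_library_plan(),
                       tier2_retention = 1, seed = 1L) {
  stopifnot(fold_enrichment > 1, baseline_freq > 0,
            n_sole + n_predominant < n_genes,
            tier2_retention > 0, tier2_retention <= 1)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  labels <- rep("NULL", n_genes)
  labels[seq_len(n_sole)] <- "SOLE_INFLO"
  labels[n_sole + seq_len(n_predominant)] <- "INFLO_PREDOMINANT"

  implanted_inflo <- baseline_freq * fold_enrichment
  freq_inflo <- rep(0, n_genes)
  freq_inflo[labels != "NULL"] <- implanted_inflo
  freq_other <- rep(0, n_genes)
  freq_other[labels == "INFLO_PREDOMINANT"] <- baseline_freq
  # remaining mass spread over null genes
  nulls <- labels == "NULL"
  freq_inflo[nulls] <- (1 - sum(freq_inflo)) / sum(nulls)
  freq_other[nulls] <- (1 - sum(freq_other)) / sum(nulls)

  profiles <- stats::setNames(
    lapply(est_tissue_classes(),
           function(t) if (t == "INFLORESCENCE") freq_inflo else freq_other),
    est_tissue_classes())
  for (p in profiles) stopifnot(abs(sum(p) - 1) < 1e-12)

  structure(list(genes = genes, truth = labels, profiles = profiles,
                 library_plan = library_plan,
                 tier2_retention = tier2_retention, seed = as.integer(seed)),
            class = "est_design")
}

#' Default library sampling plan
#'
#' Five inflorescence libraries (100,000 ESTs in all — floral tissues
#' dominate real EST collections assembled for inflorescence studies), a
#' seed pool of 60,000 ESTs over two libraries (the seed compartment is
#' typically the largest non-floral contributor), single root and leaf
#' libraries of 30,000 ESTs, and a stem pool of 30,000 ESTs split over three
#' small libraries, mirroring the skewed pool structure of public cDNA
#' library collections.
#'
#' @return Tibble `tissue_class, est_total`.
#' @export
default_library_plan <- function() {
  tibble::tribble(
    ~tissue_class,   ~est_total,
    "INFLORESCENCE", 20000L,
    "INFLORESCENCE", 20000L,
    "INFLORESCENCE", 20000L,
    "INFLORESCENCE", 20000L,
    "INFLORESCENCE", 20000L,
    "ROOT",          30000L,
    "STEM",          10000L,
    "STEM",          10000L,
    "STEM",          10000L,
    "LEAF",          30000L,
    "SEED",          30000L,
    "SEED",          30000L
  )
}

#' Null-universe variant of a design
#'
#' Same genes and library plan, no implanted genes: every tissue draws from
#' the identical uniform frequency vector. Used to measure the screen's
#' false-positive rate.
#'
#' @param design An [est_design()].
#' @return An `est_design` with all labels `NULL` and uniform profiles.
#' @export
null_design <- function(design) {
  n <- length(design$genes)
  u <- rep(1 / n, n)
  design$truth <- rep("NULL", n)
  design$profiles <- lapply(design$profiles, function(p) u)
  design
}

#' Draw a synthetic EST universe
#'
#' Each library's ESTs are one multinomial draw of size `est_total` from its
#' tissue's transcript-frequency profile; both homology tiers derive from the
#' same draws (the tier-2 matrix binomially subsamples each matched count at
#' the design's retention rate, emulating the stricter homology criterion).
#' Fully reproducible from the design seed.
#'
#' @param design An [est_design()].
#' @return A list: `libraries` (metadata tibble), `tier1` and `tier2`
#'   ([est_count_matrix()]s), `truth` (tibble `gene_id, label`).
#' @export
#' @examples
#' u <- simulate_est_universe(est_design(n_genes = 50, seed = 7))
#' colSums(u$tier1[-1]) == u$libraries$est_total
simulate_est_universe <- function(design) {
  stopifnot(inherits(design, "est_design"))
  set.seed(design$seed)
  plan <- design$library_plan
  lib_ids <- sprintf("lib%02d", seq_len(nrow(plan)))
  libraries <- est_libraries(lib_ids, plan$tissue_class, plan$est_total,
                             normalized = FALSE)
  counts <- vapply(seq_len(nrow(plan)), function(i) {
    as.integer(stats::rmultinom(1, plan$est_total[i],
                                design$profiles[[plan$tissue_class[i]]]))
  }, integer(length(design$genes)))
  colnames(counts) <- lib_ids
  tier1 <- est_count_matrix(
    dplyr::bind_cols(tibble(gene_id = design$genes), as_tibble(counts)),
    tier = "contig_90", libraries = libraries)
  t2 <- counts
  if (design$tier2_retention < 1) {
    t2[] <- stats::rbinom(length(counts), counts, design$tier2_retention)
  }
  tier2 <- est_count_matrix(
    dplyr::bind_cols(tibble(gene_id = design$genes), as_tibble(t2)),
    tier = "cds_99", libraries = libraries)
  list(libraries = libraries, tier1 = tier1, tier2 = tier2,
       truth = tibble(gene_id = design$genes, label = design$truth))
}

#' Design a synthetic RNA-seq experiment
#'
#' A designed FPKM value per gene and tissue (expanded over stages: the
#' inflorescence and vegetative tissues get three stages each, stamen and
#' pistil one), a sequencing depth per sample, and a length per gene.
#' Per-stage FPKM is the tissue's designed value in the first stage and
#' 60%/30% of it in later stages, so max-over-stages recovers the designed
#' value.
#'
#' @param fpkm_design Tibble: `gene_id` plus one numeric column per RNA-seq
#'   tissue ([rnaseq_tissues()]), the designed FPKM.
#' @param depth Mapped reads per sample (default 1e7).
#' @param gene_length_bp Transcript length per gene, recycled (default 1500).
#' @param seed Integer seed.
#' @return A list of class `rnaseq_design`.
#' @export
rnaseq_design <- function(fpkm_design, depth = 1e7, gene_length_bp = 1500,
                          seed = 1L) {
  stopifnot(all(rnaseq_tissues() %in% names(fpkm_design)),
            depth > 0, all(gene_length_bp > 0))
  structure(list(fpkm_design = as_tibble(fpkm_design),
                 depth = depth,
                 gene_length_bp = rep_len(gene_length_bp,
                                          nrow(fpkm_design)),
                 seed = as.integer(seed)),
            class = "rnaseq_design")
}

stage_plan <- function() {
  tibble(
    tissue = c(rep("INFLORESCENCE", 3), "STAMEN", "PISTIL",
               rep(c("ROOT", "LEAF", "STEM", "GRAIN"), each = 3)),
    stage = c(inflorescence_stages(), "S1", "S1",
              rep(c("T1", "T2", "T3"), times = 4)),
    scale = c(1, 0.6, 0.3, 1, 1, rep(c(1, 0.6, 0.3), times = 4))
  )
}

#' Draw synthetic RNA-seq counts
#'
#' Per gene and sample, `raw_count ~ Poisson(FPKM * length_bp * depth / 1e9)`
#' — pure sampling noise around the designed expression, the noise model the
#' downstream statistics assume. A designed FPKM of 0 always yields count 0.
#' Reproducible from the design seed.
#'
#' @param design An [rnaseq_design()].
#' @return A validated long expression tibble (with `fpkm` recomputed from
#'   the simulated counts).
#' @export
simulate_rnaseq <- function(design) {
  stopifnot(inherits(design, "rnaseq_design"))
  set.seed(design$seed)
  fd <- design$fpkm_design
  plan <- stage_plan()
  long <- tidyr::crossing(
    tibble(gene_id = fd$gene_id,
           gene_length_bp = design$gene_length_bp),
    plan
  )
  design_fpkm <- as.matrix(fd[rnaseq_tissues()])
  rownames(design_fpkm) <- fd$gene_id
  long$design_fpkm <- design_fpkm[cbind(long$gene_id, long$tissue)] *
    long$scale
  lambda <- long$design_fpkm * long$gene_length_bp * design$depth / 1e9
  long$raw_count <- stats::rpois(nrow(long), lambda)
  long$mapped_total <- as.integer(design$depth)
  validate_expression_table(
    long[, c("gene_id", "tissue", "stage", "raw_count", "mapped_total",
             "gene_length_bp")]
  )
}

#' Archetype FPKM designs for the expression groups
#'
#' One designed profile per expression subgroup with clear margins around the
#' classifier's defaults (negligible-FPKM floor 0.5; designed folds at least
#' 20x the floor), plus an all-zero `LOW_DATA` archetype and a flat
#' `UNCLASSIFIED` archetype. `n_per_group` genes are generated per archetype;
#' the returned design doubles as the truth table.
#'
#' @param n_per_group Genes per archetype (default 5).
#' @return Tibble: `gene_id`, `truth`, one column per RNA-seq tissue.
#' @export
archetype_fpkm_design <- function(n_per_group = 5) {
  arch <- tibble::tribble(
    ~truth,         ~INFLORESCENCE, ~STAMEN, ~PISTIL, ~ROOT, ~LEAF, ~STEM, ~GRAIN,
    "G1_1",         40,             1,       1,       4,     4,     4,     4,
    "G1_2",         40,             0,       0,       0,     0,     0,     0,
    "G2_1",         20,             500,     400,     5,     50,    5,     5,
    "G2_2",         20,             500,     10,      5,     50,    5,     5,
    "G3_1",         0.1,            200,     0,       0,     0,     0,     0,
    "G3_2",         50,             200,     0,       0,     0,     0,     0,
    "UNCLASSIFIED", 30,             30,      30,      30,    30,    30,    30,
    "LOW_DATA",     0,              0,       0,       0,     0,     0,     0
  )
  out <- arch[rep(seq_len(nrow(arch)), each = n_per_group), ]
  out$gene_id <- sprintf("%s_%02d", tolower(out$truth),
                         rep(seq_len(n_per_group), times = nrow(arch)))
  out[, c("gene_id", "truth", rnaseq_tissues())]
}
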