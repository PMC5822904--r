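# Canonical tissue vocabularies and the alias map between them.

#' Tissue vocabularies
#'
#' Two fixed vocabularies are used throughout the package. cDNA libraries are
#' pooled into five classes (`est_tissue_classes()`); RNA-seq samples use a
#' seven-tissue vocabulary (`rnaseq_tissues()`) in which the seed/grain
#' compartment is called `GRAIN` and the floral organs stamen and pistil are
#' profiled separately from the whole inflorescence. `vegetative_tissues()`
#' names the four RNA-seq tissues treated as the non-floral reference set.
#' The order of `rnaseq_tissues()` is the canonical tie-break order for
#' argmax operations, so all outputs are deterministic.
#'
#' @return A character vector of tissue names.
#' @export
#' @examples
#' est_tissue_classes()
est_tissue_classes <- function() {
  c("INFLORESCENCE", "ROOT", "STEM", "LEAF", "SEED")
}

#' @rdname est_tissue_classes
#' @export
rnaseq_tissues <- function() {
  c("INFLORESCENCE", "STAMEN", "PISTIL", "ROOT", "LEAF", "STEM", "GRAIN")
}

#' @rdname est_tissue_classes
#' @export
vegetative_tissues <- function() {
  c("ROOT", "LEAF", "STEM", "GRAIN")
}

#' Inflorescence developmental stages profiled by RNA-seq
#'
#' Zadoks-scale stages: Z32 (two nodes), Z39 (meiosis), Z65 (anthesis).
#'
#' @return Character vector of stage labels.
#' @export
inflorescence_stages <- function() {
  c("Z32", "Z39", "Z65")
}

#' Tissue alias table for cDNA library descriptions
#'
#' Library source descriptions in EST metadata are free text (anther, pistil,
#' ovary, palea, lemma, spike, embryo, ...). This table maps each known alias
#' to one of the five library pool classes. Floral organs and spike tissues
#' all pool into `INFLORESCENCE`; seed, embryo, kernel and grain libraries
#' form the `SEED` pool (the same compartment the RNA-seq vocabulary calls
#' `GRAIN`, see [seed_grain_map()]). Users may extend the table by row-binding
#' additional `alias`/`tissue_class` pairs; unknown aliases are an error in
#' [read_library_table()], never silently dropped.
#'
#' @return A tibble with columns `alias` and `tissue_class`.
#' @export
#' @examples
#' tissue_alias_table()
tissue_alias_table <- function() {
  tibble::tribble(
    ~alias,                 ~tissue_class,
    "inflorescence",        "INFLORESCENCE",
    "spike",                "INFLORESCENCE",
    "spikelet",             "INFLORESCENCE",
    "floret",               "INFLORESCENCE",
    "anther",               "INFLORESCENCE",
    "premeiotic anther",    "INFLORESCENCE",
    "anther at meiosis",    "INFLORESCENCE",
    "stamen",               "INFLORESCENCE",
    "pistil",               "INFLORESCENCE",
    "ovary",                "INFLORESCENCE",
    "palea",                "INFLORESCENCE",
    "lemma",                "INFLORESCENCE",
    "glume",                "INFLORESCENCE",
    "root",                 "ROOT",
    "stem",                 "STEM",
    "internode",            "STEM",
    "leaf",                 "LEAF",
    "flag leaf",            "LEAF",
    "seedling",             "LEAF",
    "crown",                "LEAF",
    "seed",                 "SEED",
    "grain",                "SEED",
    "kernel",               "SEED",
    "embryo",               "SEED",
    "immature embryo",      "SEED",
    "endosperm",            "SEED"
  )
}

#' Mapping between the EST pool and RNA-seq names of the seed compartment
#'
#' The EST library vocabulary calls the compartment `SEED`; the RNA-seq
#' vocabulary calls it `GRAIN`. One biological tissue, two names; this table
#' is the single place the correspondence is fixed.
#'
#' @return A tibble with columns `est_pool` and `rnaseq_tissue`.
#' @export
seed_grain_map <- function() {
  tibble::tibble(
    est_pool      = c("INFLORESCENCE", "ROOT", "STEM", "LEAF", "SEED"),
    rnaseq_tissue = c("INFLORESCENCE", "ROOT", "STEM", "LEAF", "GRAIN")
  )
}

# Resolve free-text tissue descriptions to pool classes; error on unknowns.
resolve_tissue_alias <- function(tissue, aliases = tissue_alias_table()) {
  key <- tolower(trimws(tissue))
  # already-canonical class names pass through
  canon <- toupper(key) %in% est_tissue_classes()
  out <- ifelse(canon, toupper(key),
                aliases$tissue_class[match(key, aliases$alias)])
  if (anyNA(out)) {
    bad <- unique(tissue[is.na(out)])
    abort(
      paste0("Unknown tissue alias(es): ", paste(bad, collapse = ", "),
             ". Extend the alias table or correct the metadata."),
      class = "estdigex_error_unknown_tissue"
    )
  }
  out
}
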