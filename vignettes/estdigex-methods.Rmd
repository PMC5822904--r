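---
title: "Digital differential expression from EST pools: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital differential expression from EST pools: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estdigex)
```

## The problem

Before deep RNA-seq, the cheapest genome-wide readout of where a gene is
expressed was the expressed sequence tag (EST): a single-pass read from a
clone drawn at random from a tissue's cDNA library. If a transcript makes up
a fraction $f$ of a library's mRNA population, the number of ESTs matching it
in a library of size $N$ is, to good approximation, a binomial draw
$\mathrm{Bin}(N, f)$. Comparing a gene's EST counts between libraries made
from different tissues is therefore a statistical comparison of expression
levels — *digital* differential expression.

estdigex implements this screen for the setting that motivated it:
identifying genes preferentially expressed in the inflorescence (the grass
flowering spike, including anthers and pistil) of allohexaploid bread wheat,
where each gene typically has homoeologous copies on the A, B and D
subgenomes. The package also implements the RNA-seq statistics used to
cross-validate candidates, a rule-based expression-group classifier, and
summary statistics over a packaged catalog of 59 inflorescence
development-related gene sets (170 gene copies).

## The sampling-probability statistic

Libraries are pooled into five tissue classes: `INFLORESCENCE`, `ROOT`,
`STEM`, `LEAF`, `SEED`. Libraries smaller than 1,000 ESTs, or subjected to
normalization/enrichment (which decouples clone frequency from transcript
abundance), are excluded by `filter_libraries()`.

For a gene with $m$ matched ESTs in an inflorescence pool of size $M$, the
pool EST frequency is $f = m/M$. For each non-inflorescence pool with $n$
matched ESTs out of $N$, the screen evaluates the binomial point probability

$$P \;=\; \binom{N}{n} f^{\,n} (1-f)^{N-n},$$

the probability of the observed count if the gene were expressed in that
tissue at the inflorescence level. `sampling_probability()` computes this in
log space (log-gamma for the coefficient, `log1p` for the $(1-f)$ term) so
pool sizes in the tens of thousands are handled without over/underflow; a
`log = TRUE` argument returns the log probability directly for extreme
tails. Edge conventions are exact: $f=0$ gives $P=1$ iff $n=0$; $f=1$ gives
$P=1$ iff $n=N$.

A gene passes the screen (`screen_gene()`, `run_screen()`) by one of two
routes:

* **SOLE** — matched ESTs come solely from inflorescence libraries
  ($m>0$, all other pools $n=0$). Threshold-independent.
* **SIGNIFICANT** — $m>0$ and, for *each* non-inflorescence pool with
  $N>0$, either $n=0$ or $P \le$ threshold.

Default thresholds are $10^{-4}$ for the first-pass screen on contig-level
matches (tier `contig_90`) and $10^{-2}$ for the confirmation screen on
coding-sequence matches at the stricter homology cutoff (tier `cds_99`).
Empty pools ($N=0$) never block a pass: a tissue without libraries carries
no evidence either way, and small pools (real stem pools can hold only a few
libraries) must not crash or bias the screen.

Three ambiguities in this procedure are resolved as package defaults, each
with an escape hatch:

* **Point probability, not a tail.** The statistic is the pmf exactly as
  written above. A lower-tail variant ($\sum_{k \le n} P(k)$) is available
  via `tail_sum = TRUE` for sensitivity analysis but is never the default.
* **Per-pool, not merged.** "More than in any other tissue" is read as a
  condition against each pool separately; `merged_pool = TRUE` tests one
  combined non-inflorescence pool instead.
* **Directionality guard.** The pmf is two-sided in spirit: a pool can have
  a tiny $P$ because the gene is *over*represented there. By default a pool
  with $n>0$ must also satisfy $n/N < f$; `direction_guard = FALSE`
  disables this.

No multiple-testing correction is applied; the number of genes tested is
attached to the result (`attr(x, "n_tested")`) so users can adjust post hoc.

### Power of the point probability, and the generator defaults

The point pmf has a quirk that matters for calibration: under enrichment the
expected count in a background pool under $f$ is $\lambda = fN$, and for an
observed $n$ *far below* $\lambda$ — the very signature of enrichment — the
point probability $P(n)$ is small only when $\lambda$ itself is large. For
example $P(1) = \lambda e^{-\lambda}$ (to Poisson accuracy) crosses
$10^{-4}$ only at $\lambda \approx 11.7$, and $P(3)$ only at
$\lambda \approx 16$. A pool whose expected count under the inflorescence
frequency is below ~16 can therefore fail a genuinely enriched gene whenever
background sampling delivers one to three stray matches.

The synthetic-data defaults are chosen with this in mind. `est_design()`
implants 20 enriched genes (10 sole-inflorescence, 10 predominant) at
100-fold enrichment over a baseline frequency of $10^{-5}$, with an
inflorescence pool of 100,000 ESTs (five libraries) and non-inflorescence
pools of 30,000–60,000 ESTs. An implanted gene then has expected $m = 100$,
$f \approx 10^{-3}$, and $\lambda = fN \approx 30$ in each 30,000-EST pool —
comfortably past the power cliff — while a predominant gene's true
background rate per pool is $0.3$ matches, so most pools see $n = 0$.
Under these conditions tier-1 recovery of implanted genes is essentially
complete and no null gene passes (both checked by the test suite and
recomputed by `scripts/acceptance.R`). Designs with expected $m$ near 15–20
sit on the cliff and recover only ~85–95% of implanted genes; that regime is
reachable by lowering `fold_enrichment` or the library plan if one wants to
study it.

The pool structure itself mirrors public EST collections: floral libraries
dominate (five inflorescence libraries), the seed compartment is the largest
non-floral contributor (two libraries), and the stem pool is split across
three small libraries.

## RNA-seq statistics

Expression tables are long-form: one row per gene, tissue and developmental
stage, carrying the raw mapped-read count, the sample's total mapped reads,
and the gene length. The seven-tissue vocabulary is `INFLORESCENCE` (stages
Z32 two-nodes, Z39 meiosis, Z65 anthesis), `STAMEN`, `PISTIL`, `ROOT`,
`LEAF`, `STEM`, `GRAIN`; the EST vocabulary's `SEED` pool and the RNA-seq
`GRAIN` tissue are the same compartment (`seed_grain_map()`).

* **FPKM** (`fpkm()`): $c \cdot 10^9 / (L \cdot D)$ for count $c$, length
  $L$ bp, depth $D$.
* **Max over stages.** Wherever a tissue has several profiled stages, the
  stage with maximal FPKM represents the tissue (`tissue_stage_max()`), and
  that same stage's count pair feeds any significance test — value and test
  always come from the same sample.
* **RES** (`res_specificity()`): for focal tissue A, with B the most highly
  expressed other tissue, $\mathrm{RES} = (e_A - e_B)/e_A$. RES $\le 1$,
  equals 1 iff $e_B = 0$, can be negative, is undefined at $e_A = 0$, and is
  scale-invariant. Ties for B are broken by the canonical tissue order above
  so output is deterministic.
* **Chi-square test** (`chi_square_diff()`): Pearson on the 2×2 table of
  count vs remaining depth in the two samples, df = 1, no Yates correction
  (the common default for deep-count proportions; `correct = TRUE` is
  available). Raw counts and depths are compared, not length-normalized
  values: both samples see the same gene, so length cancels from the
  proportion comparison. Significance is strict: $p < \alpha$ with
  $\alpha = 0.05$. Degenerate tables (both proportions identically 0 or 1)
  return statistic 0, $p = 1$.
* **Heat-map quotient** (`relative_abundance()`): per-tissue max-stage FPKM
  divided by the mean over all genes, then $\log_2(q + \varepsilon)$ with
  $\varepsilon = 0.01$. Base and pseudocount are choices (only "a log
  transformation" is canonical) and both are arguments.
* **qPCR fold change** (`ddct_fold_change()`): $2^{-\Delta\Delta C_T}$.

## The expression-group classifier

`classify_genes()` formalizes a six-subgroup taxonomy over FPKM profiles and
pairwise chi-square calls, with vegetative tissues {ROOT, LEAF, STEM,
GRAIN}, a negligible-FPKM floor (default 0.5 — "negligible" is not
quantified anywhere authoritative, so the floor is an argument and the
sensitivity of group counts to it is easy to tabulate), and evaluation order
G3 → G2 → G1:

* **LOW_DATA**: every tissue below the floor (too few reads to classify).
* **G3** (stamen-specific): all vegetative below the floor, stamen at or
  above it and significantly higher than each vegetative tissue. G3-1 if
  the inflorescence is also below the floor, G3-2 if it is significantly
  higher than each vegetative tissue.
* **G2** (floral-enriched over a vegetative baseline): at least one
  vegetative tissue at or above the floor, and stamen or pistil
  significantly higher than every vegetative tissue. G2-1 when the pistil
  condition holds, G2-2 otherwise.
* **G1** (inflorescence-predominant): inflorescence significantly higher
  than each vegetative tissue. G1-2 when stamen, pistil and all vegetative
  tissues are below the floor, G1-1 otherwise.
* **UNCLASSIFIED**: no clause fires.

The precedence resolves profiles satisfying several clauses; the returned
evidence list records every clause evaluated, so any assignment can be
re-derived and audited. RES values for stamen, pistil and inflorescence are
recomputed for reporting but are never a gating criterion — in published
practice the high stamen RES of the stamen-specific group is an *outcome*
of the grouping, not an input. Whether a historical grouping of this kind
was rule-based or manual is unknowable from printed descriptions; this
classifier is a deterministic formalization, and its counts on real data
may legitimately differ from a manual grouping.

## The homoeolog catalog

`load_catalog()` ships a transcription of the printed chromosome
distribution of the 59 gene sets, one row per subgenome slot, with absent
slots coded `a` (gene not found), `b` (genomic DNA present, no EST
support), or `c` (present but not inflorescence-predominant). Two
documented corrections are applied on load, each with a message: the two
rows of a set duplicated on 6A and 6D merge into one set with two copies on
each, and a set identifier printed twice is relabelled to the otherwise
missing identifier (the printed totals — 59 sets, 170 genes — are
consistent only under that reading).

`summarize_catalog()` computes totals, per-group gene counts and
percentages, presence classes and duplication sets. Percentages are of gene
*copies* (not sets), with group membership a property of each chromosome
token — a set translocated across groups contributes per chromosome — and
are rounded half-up to one decimal. These are the only conventions under
which the summary reproduces the printed 68.2% (groups 1+3+6) and 5.3%
(group 4) exactly, which the test suite asserts.

## The synthetic-data generator

`simulate_est_universe()` draws each library as one multinomial sample of
size `est_total` from its tissue's transcript-frequency vector; both
homology tiers derive from the same draws, with the tier-2 matrix optionally
thinned by a binomial retention rate (default 1, so tier effects are
opt-in). `simulate_rnaseq()` draws each count as
$\mathrm{Poisson}(\mathrm{FPKM} \cdot L \cdot D / 10^9)$. Poisson noise is
the model the screen's own statistics assume — nothing beyond sampling
noise — which is precisely what makes recovery tests interpretable as
checks of the decision rules rather than of a noise model. Real RNA-seq has
biological overdispersion, library-preparation biases and multi-mapping
ambiguity that the generator deliberately omits, so passing recovery tests
demonstrate correctness of the statistics and rules, not field performance
on real tissue panels. All draws are reproducible from a single integer
seed per design.

Archetype RNA-seq designs (`archetype_fpkm_design()`) place one profile per
subgroup with clear margins: designed FPKM at least 20× the 0.5 floor for
"expressed" tissues, depth $10^7$, gene length 1,500 bp, so the designed
fold is resolved by counting noise with overwhelming probability. The
G3-1 archetype keeps a token inflorescence FPKM of 0.1 to exercise the
floor; the `LOW_DATA` archetype is all-zero.

## Problem sizes and runtime

The test suite and acceptance script run the screen on 200-gene universes
with ~250,000 simulated ESTs, classify 40 archetype genes at depth $10^7$,
and evaluate the statistic on a 522-point frozen grid ($N$ up to $10^4$)
computed once with exact rational arithmetic at 30 significant digits.
These sizes resolve every claimed calibration property while keeping a full
run in seconds on a laptop; all of them scale up linearly through the
design objects if heavier studies are wanted.

## Known limitations

* Homology matching is upstream: the package consumes matched-count
  matrices labelled with a tier and cannot detect upstream mis-assignment
  (e.g. cross-homoeolog EST matches below the chosen identity cutoff).
* EST counts are integers end-to-end; multi-mapping ESTs are not
  fractionally assigned.
* The screen's statistic is a point probability and inherits the power
  cliff described above; users with small pools should prefer the tier-2
  threshold or the tail-sum variant and interpret borderline calls
  cautiously.
* The classifier's six-group taxonomy is fixed; it does not discover groups.
* No isoform-level quantification, TPM, or negative-binomial dispersion in
  the default generator (an NB option would sit naturally in
  `rnaseq_design()` but robustness to overdispersion is not a claim this
  package currently tests).
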