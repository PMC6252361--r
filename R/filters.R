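#' Standard rare-frequency filter
#'
#' A variant passes when every *reported* population allele frequency
#' (1000 Genomes, ExAC, EVS) is at or below `cfg$af_standard_max`
#' (inclusive, default 0.5%). The interpretation is conjunctive: a variant
#' common in any one database fails. Absent frequencies are ignored --
#' unobserved means rare, and novel variants must survive.
#'
#' @param v Data frame of variants with columns `af_1000g`, `af_exac`,
#'   `af_evs` (`NA` = absent).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per variant row.
#' @export
passes_standard_frequency <- function(v, cfg = filter_config()) {
  af_ok <- function(af) is.na(af) | af <= cfg$af_standard_max
  af_ok(v$af_1000g) & af_ok(v$af_exac) & af_ok(v$af_evs)
}

#' Permissive high-carrier-frequency filter for recessive/X-linked search
#'
#' Complementary to the standard filter: recessive and X-linked candidate
#' alleles may segregate at appreciable carrier frequency, so the ceiling
#' is relaxed to `cfg$af_permissive_max` (inclusive, default 10%) provided
#' ExAC reports no homozygous genotypes -- and, for X-chromosome variants
#' outside the PAR, no hemizygous genotypes either. Absent counts are
#' treated like zero (no carriers reported).
#'
#' @inheritParams passes_standard_frequency
#' @return Logical vector.
#' @export
passes_permissive_recessive_frequency <- function(v, cfg = filter_config()) {
  af_ok <- function(af) is.na(af) | af <= cfg$af_permissive_max
  hom_ok <- is.na(v$exac_hom_count) | v$exac_hom_count == 0L
  on_x <- is_hemizygous_region(v$chrom, v$pos, cfg) & v$chrom == "chrX"
  hemi_ok <- !on_x | is.na(v$exac_hemi_count) | v$exac_hemi_count == 0L
  af_ok(v$af_1000g) & af_ok(v$af_exac) & af_ok(v$af_evs) & hom_ok & hemi_ok
}

#' Predicted-deleterious consequence filter
#'
#' A variant is retained when its consequence category is one of the
#' loss-of-function/protein-altering classes (deleterious-flagged missense
#' SNV, frameshift, start/stop codon changes) or when it is a
#' splice-region variant within `cfg$splice_window_bp` (default +/-7 bp)
#' of the nearest exon boundary. A splice-region variant with no reported
#' splice distance cannot be placed inside the window and is treated as
#' not deleterious.
#'
#' @param v Data frame of variants with columns `consequence` and
#'   `splice_distance`.
#' @param cfg A [filter_config()].
#' @return Logical vector.
#' @export
is_predicted_deleterious <- function(v, cfg = filter_config()) {
  direct <- v$consequence %in% cfg$deleterious_consequences
  splice <- v$consequence == "splice_region" &
    !is.na(v$splice_distance) &
    abs(v$splice_distance) <= cfg$splice_window_bp
  direct | splice
}

#' Per-variant filter trail
#'
#' Records the outcome of every filter predicate for every variant: the
#' audit trail carried into candidate sets and reports, and the surface
#' the brute-force oracle cross-checks.
#'
#' @param v Tibble of variants (see [read_trio_vcf()]).
#' @param cfg A [filter_config()].
#' @param panel Optional [gene_panel()]; adds an `in_scope` column.
#' @return Tibble with columns `variant_id`, `in_scope`, `deleterious`,
#'   `std_freq`, `perm_freq`, `symbolic`.
#' @export
filter_trail <- function(v, cfg = filter_config(), panel = NULL) {
  tibble::tibble(
    variant_id = v$variant_id,
    in_scope = if (is.null(panel)) TRUE else panel_contains(panel, v$gene),
    deleterious = is_predicted_deleterious(v, cfg),
    std_freq = passes_standard_frequency(v, cfg),
    perm_freq = passes_permissive_recessive_frequency(v, cfg),
    symbolic = if ("symbolic" %in% names(v)) v$symbolic else FALSE
  )
}
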