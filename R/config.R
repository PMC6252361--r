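#' Consequence categories understood by the consequence filter
#'
#' The vocabulary an upstream annotator is expected to collapse its
#' consequence calls into. `snv_deleterious_missense` stands for a missense
#' single-nucleotide variant that the annotator flagged as deleterious;
#' plain (tolerated) missense calls should arrive as `other`.
#'
#' @export
CONSEQUENCE_CATEGORIES <- c(
  "snv_deleterious_missense", "frameshift", "start_lost", "stop_gained",
  "stop_lost", "splice_region", "synonymous", "intronic", "intergenic",
  "other"
)

#' Consequence categories treated as predicted deleterious outright
#'
#' `splice_region` is handled separately via the splice-distance window.
#' @export
DELETERIOUS_CONSEQUENCES <- c(
  "snv_deleterious_missense", "frameshift", "start_lost", "stop_gained",
  "stop_lost"
)

#' Pseudoautosomal regions (GRCh37 chrX coordinates)
#'
#' PAR1/PAR2 masks; variants on chrX inside these intervals are treated as
#' autosomal (diploid in both sexes). Build-configurable: pass any
#' data frame with columns `chrom`, `start`, `end` to [filter_config()].
#'
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
par_regions_grch37 <- function() {
  tibble::tibble(
    chrom = "chrX",
    start = c(60001L, 154931044L),
    end   = c(2699520L, 155260560L)
  )
}

#' Default mapping from pipeline annotation fields to VCF INFO keys
#'
#' Annotation field names are configurable because annotated VCFs from
#' different annotators use different INFO keys.
#'
#' @return Named list mapping internal field names to INFO keys.
#' @export
default_field_map <- function() {
  list(
    gene             = "GENE",
    consequence      = "CSQ_CAT",
    splice_distance  = "SPLICE_DIST",
    af_1000g         = "AF_1000G",
    af_exac          = "AF_EXAC",
    af_evs           = "AF_EVS",
    exac_hom_count   = "EXAC_HOM",
    exac_hemi_count  = "EXAC_HEMI",
    known_pathogenic = "KNOWN_PATH"
  )
}

#' Filter and pipeline configuration
#'
#' Bundles every tunable threshold of the triage workflow. Defaults follow
#' rare-disease diagnostic practice: candidate variants must be rare
#' (frequency at or below 0.5% in every population database that reports
#' them), with a permissive 10% ceiling for recessive/X-linked candidates
#' that have no homozygous (or, on X, hemizygous) carriers in ExAC; splice
#' region variants count as deleterious within +/-7 bp of an exon boundary.
#'
#' @param af_standard_max Standard rare-frequency ceiling (fraction,
#'   inclusive). Default 0.005.
#' @param af_permissive_max Permissive ceiling for recessive/X-linked
#'   candidates (fraction, inclusive). Default 0.10.
#' @param splice_window_bp Splice-region window in bp around exon
#'   boundaries. Default 7.
#' @param deleterious_consequences Consequence categories treated as
#'   deleterious outright (splice_region is governed by the window).
#' @param min_gq,min_dp Genotype-quality gate applied to all three samples
#'   at read time. Defaults GQ >= 20, depth >= 8.
#' @param allow_unresolved_phase If `TRUE`, heterozygous variants seen in
#'   both parents (parental origin unresolved) may participate in
#'   compound-heterozygous pairs. Default `FALSE`: unphaseable pairs cannot
#'   be shown to be in trans.
#' @param par_regions Data frame of pseudoautosomal intervals
#'   (`chrom`, `start`, `end`); treated as autosomal.
#' @param field_map Named list mapping internal annotation fields to VCF
#'   INFO keys; see [default_field_map()].
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(af_standard_max = 0.005,
                          af_permissive_max = 0.10,
                          splice_window_bp = 7L,
                          deleterious_consequences = DELETERIOUS_CONSEQUENCES,
                          min_gq = 20L,
                          min_dp = 8L,
                          allow_unresolved_phase = FALSE,
                          par_regions = par_regions_grch37(),
                          field_map = default_field_map()) {
  stopifnot(
    is.numeric(af_standard_max), length(af_standard_max) == 1L,
    is.numeric(af_permissive_max), length(af_permissive_max) == 1L,
    is.numeric(splice_window_bp), splice_window_bp >= 0
  )
  if (!(af_standard_max >= 0 && af_standard_max <= af_permissive_max &&
        af_permissive_max <= 1)) {
    stop("require 0 <= af_standard_max <= af_permissive_max <= 1",
         call. = FALSE)
  }
  bad <- setdiff(deleterious_consequences, CONSEQUENCE_CATEGORIES)
  if (length(bad)) {
    stop("unknown consequence categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  par_regions <- tibble::as_tibble(par_regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(par_regions)))
  structure(
    list(
      af_standard_max = af_standard_max,
      af_permissive_max = af_permissive_max,
      splice_window_bp = as.integer(splice_window_bp),
      deleterious_consequences = deleterious_consequences,
      min_gq = as.integer(min_gq),
      min_dp = as.integer(min_dp),
      allow_unresolved_phase = isTRUE(allow_unresolved_phase),
      par_regions = par_regions,
      field_map = utils::modifyList(default_field_map(), field_map)
    ),
    class = "filter_config"
  )
}

#' Read / write a filter configuration as JSON
#'
#' @param path Path to a JSON file.
#' @return `read_filter_config()` returns a [filter_config()] object.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(filter_config)))]
  if (!is.null(args$par_regions)) {
    args$par_regions <- tibble::as_tibble(args$par_regions)
  }
  if (!is.null(args$field_map)) args$field_map <- as.list(args$field_map)
  do.call(filter_config, args)
}

#' @rdname read_filter_config
#' @param cfg A [filter_config()] object.
#' @export
write_filter_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "filter_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Is a position inside a pseudoautosomal region?
#'
#' @param chrom,pos Vectors of normalized chromosome labels and 1-based
#'   positions.
#' @param par_regions Data frame of PAR intervals.
#' @return Logical vector.
#' @export
in_par <- function(chrom, pos, par_regions) {
  out <- rep(FALSE, length(chrom))
  for (i in seq_len(nrow(par_regions))) {
    out <- out | (chrom == par_regions$chrom[i] &
                    pos >= par_regions$start[i] & pos <= par_regions$end[i])
  }
  out
}

# TRUE where a variant is hemizygous territory for a male sample:
# chrX outside the PAR masks, or chrY.
is_hemizygous_region <- function(chrom, pos, cfg) {
  (chrom == "chrX" & !in_par(chrom, pos, cfg$par_regions)) | chrom == "chrY"
}
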