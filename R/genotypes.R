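#' Trio genotype states
#'
#' Every genotype in the pipeline is one of these five states; no raw VCF
#' GT string escapes the data model. `hemi_alt` is legal only on chrX
#' outside the pseudoautosomal regions (or on chrY) for a male sample.
#'
#' @export
GT_STATES <- c("hom_ref", "het", "hom_alt", "hemi_alt", "missing")

# Collapse a biallelic GT string ("0/1", "1|1", "1", "./.", ...) to a raw
# diploid/haploid state, ignoring sex and chromosome context.
gt_string_to_state <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep("missing", length(gt))
  out[gt %in% "0/0"] <- "hom_ref"
  out[gt %in% c("0/1", "1/0")] <- "het"
  out[gt %in% "1/1"] <- "hom_alt"
  out[gt %in% "0"] <- "haploid_ref"
  out[gt %in% "1"] <- "haploid_alt"
  out
}

#' Encode raw GT strings as trio genotype states
#'
#' Maps biallelic VCF GT strings to the five-state genotype model, taking
#' sample sex and chromosomal context into account: on chrX outside the PAR
#' (or on chrY), alt calls in a male sample -- haploid `1` or diploid-coded
#' `1/1` -- become `hemi_alt`. Haploid calls in any other context (or in a
#' female/unknown-sex sample) cannot be interpreted and become `missing`.
#' Any GT containing a `.` is `missing`.
#'
#' @param gt Character vector of biallelic GT strings.
#' @param sex Sample sex: `"male"`, `"female"` or `"unknown"` (length 1).
#' @param chrom,pos Normalized chromosome labels and positions, recycled
#'   against `gt`.
#' @param cfg A [filter_config()] (supplies the PAR masks).
#' @return Character vector of [GT_STATES].
#' @export
encode_genotypes <- function(gt, sex, chrom, pos, cfg = filter_config()) {
  state <- gt_string_to_state(gt)
  hemi_region <- is_hemizygous_region(chrom, pos, cfg)
  male <- identical(sex, "male")
  if (male) {
    state[hemi_region & state %in% c("haploid_alt", "hom_alt")] <- "hemi_alt"
    state[hemi_region & state %in% c("haploid_ref", "hom_ref")] <- "hom_ref"
  }
  # haploid calls surviving outside a male hemizygous context are
  # uninterpretable under the trio model
  state[!state %in% GT_STATES] <- "missing"
  state
}

# Inverse of encode_genotypes for the VCF writer: state -> GT string.
state_to_gt_string <- function(state, sex, chrom, pos, cfg) {
  hemi_region <- is_hemizygous_region(chrom, pos, cfg)
  male <- identical(sex, "male")
  out <- character(length(state))
  out[state == "hom_ref"] <- "0/0"
  out[state == "het"] <- "0/1"
  out[state == "hom_alt"] <- "1/1"
  out[state == "hemi_alt"] <- "1"
  out[state == "missing"] <- "./."
  if (male) {
    out[hemi_region & state == "hom_ref"] <- "0"
  }
  out
}

# Alleles a parent can transmit, per genotype state. Returns a list of
# integer vectors; NULL marks an untestable (missing) genotype.
transmissible_alleles <- function(state) {
  lapply(state, function(s) {
    switch(s,
      hom_ref = 0L,
      het = c(0L, 1L),
      hom_alt = 1L,
      hemi_alt = 1L,
      missing = NULL,
      NULL
    )
  })
}
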