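MODEL_LEVELS <- c("de_novo", "ar_homozygous", "ar_compound_het", "x_linked")

empty_calls <- function() {
  tibble::tibble(
    model = character(), variant_id = character(),
    partner_id = NA_character_[0], gene = character(), chrom = character(),
    pos = integer(), parental_origin = character(),
    partner_origin = NA_character_[0], known_pathogenic = logical(),
    max_af = numeric(), flags = character()
  )
}

call_row <- function(v, model, origin, partner = NULL, flags = "") {
  tibble::tibble(
    model = model,
    variant_id = v$variant_id,
    partner_id = if (is.null(partner)) NA_character_ else partner$variant_id,
    gene = v$gene,
    chrom = v$chrom,
    pos = as.integer(v$pos),
    parental_origin = origin,
    partner_origin = if (is.null(partner)) NA_character_ else partner$origin,
    known_pathogenic = if (is.null(partner)) v$known_pathogenic else
      (v$known_pathogenic | partner$known_pathogenic),
    max_af = if (is.null(partner)) v$max_af else
      pmax(v$max_af, partner$max_af, na.rm = TRUE),
    flags = flags
  )
}

#' Classify the parental origin of a proband heterozygous variant
#'
#' Trio-implied phasing: a het variant carried by exactly one parent has a
#' resolved origin; carried by both parents it is `unresolved` (it cannot
#' be assigned to a haplotype from the trio alone); carried by neither it
#' is `none` (apparent de novo); `untestable` when a parental genotype is
#' missing.
#'
#' @param mother_gt,father_gt Genotype states (see [GT_STATES]).
#' @return Character vector over
#'   `{maternal, paternal, unresolved, none, untestable}`.
#' @export
classify_parental_origin <- function(mother_gt, father_gt) {
  mother_carrier <- mother_gt %in% c("het", "hom_alt")
  father_carrier <- father_gt %in% c("het", "hom_alt", "hemi_alt")
  out <- rep("none", length(mother_gt))
  out[mother_carrier & !father_carrier] <- "maternal"
  out[!mother_carrier & father_carrier] <- "paternal"
  out[mother_carrier & father_carrier] <- "unresolved"
  out[mother_gt == "missing" | father_gt == "missing"] <- "untestable"
  out
}

#' De novo model
#'
#' Calls a variant de novo when the proband is heterozygous and both
#' parents are homozygous reference. A homozygous-alt proband with
#' homozygous-reference parents would require two independent mutation
#' events and is flagged Mendelian-inconsistent instead of called. A
#' missing parental genotype makes the variant untestable, never a call.
#'
#' @param v Tibble of variants with genotype-state columns.
#' @return Tibble of model calls (possibly empty).
#' @export
call_de_novo <- function(v) {
  hit <- v$proband_gt == "het" & v$mother_gt == "hom_ref" &
    v$father_gt == "hom_ref"
  if (!any(hit)) return(empty_calls())
  call_row(v[hit, , drop = FALSE], "de_novo", "none")
}

#' Autosomal recessive homozygous model
#'
#' Calls a variant when the proband is homozygous alt and both parents are
#' heterozygous carriers. On chrX outside the PAR the model applies to a
#' female proband with the X-specific transmitting configuration: mother
#' heterozygous, father hemizygous alt. A homozygous proband with a
#' non-carrier parent is Mendelian-inconsistent, not a call; missing
#' parental genotypes make the variant untestable.
#'
#' @param v Tibble of variants.
#' @param ped A [pedigree()] (needed for the female-X configuration).
#' @param cfg A [filter_config()] (PAR masks).
#' @return Tibble of model calls.
#' @export
call_ar_homozygous <- function(v, ped, cfg = filter_config()) {
  hemi_region <- is_hemizygous_region(v$chrom, v$pos, cfg)
  auto <- !hemi_region &
    v$proband_gt == "hom_alt" & v$mother_gt == "het" & v$father_gt == "het"
  fem_x <- hemi_region & v$chrom == "chrX" &
    identical(ped$proband_sex, "female") &
    v$proband_gt == "hom_alt" & v$mother_gt == "het" &
    v$father_gt == "hemi_alt"
  out <- empty_calls()
  if (any(auto)) {
    out <- dplyr::bind_rows(out, call_row(v[auto, , drop = FALSE],
                                          "ar_homozygous", "biparental"))
  }
  if (any(fem_x)) {
    out <- dplyr::bind_rows(out, call_row(v[fem_x, , drop = FALSE],
                                          "ar_homozygous", "biparental",
                                          flags = "x_recessive_female"))
  }
  out
}

#' X-linked model (male hemizygous proband)
#'
#' For a male proband and a chrX variant outside the PAR: calls the
#' variant when the proband is hemizygous alt and the father does not
#' carry it. Origin is maternal when the mother is a heterozygous carrier;
#' a non-carrier mother forces a de novo event on X, which is still called
#' but flagged `de_novo_on_X`. Affected females on X are handled by the
#' autosomal recessive operations ([call_ar_homozygous()],
#' [call_compound_het()]). Proband sex must be known; otherwise no call.
#'
#' @inheritParams call_ar_homozygous
#' @return Tibble of model calls.
#' @export
call_x_linked <- function(v, ped, cfg = filter_config()) {
  if (!identical(ped$proband_sex, "male")) return(empty_calls())
  on_x <- v$chrom == "chrX" & is_hemizygous_region(v$chrom, v$pos, cfg)
  father_ref <- v$father_gt == "hom_ref"
  maternal <- on_x & v$proband_gt == "hemi_alt" & father_ref &
    v$mother_gt == "het"
  denovo_x <- on_x & v$proband_gt == "hemi_alt" & father_ref &
    v$mother_gt == "hom_ref"
  out <- empty_calls()
  if (any(maternal)) {
    out <- dplyr::bind_rows(out, call_row(v[maternal, , drop = FALSE],
                                          "x_linked", "maternal"))
  }
  if (any(denovo_x)) {
    out <- dplyr::bind_rows(out, call_row(v[denovo_x, , drop = FALSE],
                                          "x_linked", "none",
                                          flags = "de_novo_on_X"))
  }
  out
}

#' Autosomal recessive compound heterozygous model
#'
#' Within each gene, pairs proband-heterozygous variants whose trio-implied
#' parental origins are opposite (one maternal, one paternal): the trans
#' configuration disabling both gene copies. Pairs from the same parent
#' (cis) are never reported. Variants heterozygous in both parents have
#' unresolved origin and are excluded unless
#' `cfg$allow_unresolved_phase = TRUE`, in which case an unresolved variant
#' may pair with any other het in the gene and the pair is flagged
#' `phase_unresolved`. Each unordered pair is reported once, anchored at
#' the lower genomic coordinate.
#'
#' @param v Tibble of variants (any genes; grouped internally).
#' @param ped A [pedigree()].
#' @param cfg A [filter_config()].
#' @return Tibble of model calls, one row per reported pair.
#' @export
call_compound_het <- function(v, ped, cfg = filter_config()) {
  hets <- v[v$proband_gt == "het" & !is.na(v$gene) & v$gene != "", ,
            drop = FALSE]
  if (!nrow(hets)) return(empty_calls())
  hets$origin <- classify_parental_origin(hets$mother_gt, hets$father_gt)
  out <- list()
  for (g in unique(hets$gene)) {
    gv <- hets[hets$gene == g, , drop = FALSE]
    gv <- gv[order(gv$pos, gv$alt), , drop = FALSE]
    if (nrow(gv) < 2L) next
    for (i in seq_len(nrow(gv) - 1L)) {
      for (j in seq(i + 1L, nrow(gv))) {
        oi <- gv$origin[i]; oj <- gv$origin[j]
        trans <- (oi == "maternal" && oj == "paternal") ||
          (oi == "paternal" && oj == "maternal")
        unres <- cfg$allow_unresolved_phase &&
          ((oi == "unresolved" && oj %in% c("maternal", "paternal",
                                            "unresolved")) ||
             (oj == "unresolved" && oi %in% c("maternal", "paternal",
                                              "unresolved")))
        if (trans || unres) {
          a <- gv[i, , drop = FALSE]; b <- gv[j, , drop = FALSE]
          row <- call_row(a, "ar_compound_het", a$origin, partner = b,
                          flags = if (unres && !trans) "phase_unresolved"
                                  else "")
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  if (!length(out)) return(empty_calls())
  dplyr::bind_rows(out)
}

#' Shortlist lone deleterious heterozygotes in recessive panel genes
#'
#' In the phase I analysis, a single predicted-deleterious heterozygous
#' variant in a gene with a recessive mode of inheritance is shortlisted
#' for manual structural-variant review (a second, undetected hit may sit
#' on the other haplotype). Hets that already participate in a trans
#' compound-het pair are handled by that model and excluded here.
#'
#' @param v Tibble of variants already restricted to deleterious,
#'   frequency-passing candidates.
#' @param gene_moi Named character vector mapping gene symbol (upper case)
#'   to mode of inheritance; only `"recessive"` genes are shortlisted.
#' @param ped A [pedigree()].
#' @param cfg A [filter_config()].
#' @return Tibble with columns `variant_id`, `gene`, `chrom`, `pos`,
#'   `reason`.
#' @export
shortlist_single_hets <- function(v, gene_moi, ped, cfg = filter_config()) {
  empty <- tibble::tibble(variant_id = character(), gene = character(),
                          chrom = character(), pos = integer(),
                          reason = character())
  if (!nrow(v)) return(empty)
  rec_genes <- names(gene_moi)[gene_moi == "recessive"]
  cand <- v[v$proband_gt == "het" & toupper(v$gene) %in% rec_genes, ,
            drop = FALSE]
  if (!nrow(cand)) return(empty)
  pairs <- call_compound_het(v, ped, cfg)
  paired <- unique(c(pairs$variant_id, pairs$partner_id))
  cand <- cand[!cand$variant_id %in% paired, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  tibble::tibble(
    variant_id = cand$variant_id,
    gene = cand$gene,
    chrom = cand$chrom,
    pos = as.integer(cand$pos),
    reason = "single deleterious het in recessive-MOI panel gene"
  )
}

#' Trio Mendelian-consistency check
#'
#' Classifies each variant's trio genotype configuration:
#' `consistent` when the proband genotype can arise from the parental
#' genotypes under biparental inheritance (with hemizygous transmission on
#' male X), `de_novo_het` for the canonical single-allele de novo
#' configuration (het proband, both parents homozygous reference --
#' labelled separately from plain inconsistency), `inconsistent`
#' otherwise, and `untestable` when any genotype involved is missing.
#'
#' @param v Tibble of variants with genotype-state columns.
#' @param ped A [pedigree()].
#' @param cfg A [filter_config()].
#' @return Character vector over
#'   `{consistent, de_novo_het, inconsistent, untestable}`.
#' @export
mendelian_consistency <- function(v, ped, cfg = filter_config()) {
  n <- nrow(v)
  out <- character(n)
  hemi_region <- is_hemizygous_region(v$chrom, v$pos, cfg)
  m_all <- transmissible_alleles(v$mother_gt)
  f_all <- transmissible_alleles(v$father_gt)
  for (i in seq_len(n)) {
    p <- v$proband_gt[i]
    m <- m_all[[i]]; f <- f_all[[i]]
    if (p == "missing" || is.null(m) || is.null(f)) {
      out[i] <- "untestable"
      next
    }
    male_hemi <- hemi_region[i] && identical(ped$proband_sex, "male")
    if (male_hemi && p %in% c("hemi_alt", "hom_ref")) {
      # male X: proband allele comes from the mother only
      want <- if (p == "hemi_alt") 1L else 0L
      out[i] <- if (want %in% m) "consistent" else "inconsistent"
      next
    }
    ok <- switch(p,
      hom_ref = (0L %in% m) && (0L %in% f),
      het = ((0L %in% m) && (1L %in% f)) || ((1L %in% m) && (0L %in% f)),
      hom_alt = (1L %in% m) && (1L %in% f),
      hemi_alt = (1L %in% m),  # hemizygous outside male context: maternal X
      FALSE
    )
    if (ok) {
      out[i] <- "consistent"
    } else if (p == "het" && v$mother_gt[i] == "hom_ref" &&
                 v$father_gt[i] == "hom_ref") {
      out[i] <- "de_novo_het"
    } else {
      out[i] <- "inconsistent"
    }
  }
  out
}
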