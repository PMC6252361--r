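#' Toy genome used by the synthetic cohort generator
#'
#' Four 1-Mb contigs (chr1, chr2, chr7, chrX); chrX carries a toy
#' pseudoautosomal segment at its start (see [toy_par_regions()]).
#' Genome-scale variant counts are deliberately not reproduced: the
#' generator emulates the statistical structure the filters assume, in
#' seconds, not the size of a real genome.
#'
#' @return Tibble `chrom`/`length`.
#' @export
toy_contigs <- function() {
  tibble::tibble(chrom = c("chr1", "chr2", "chr7", "chrX"),
                 length = rep(1000000L, 4))
}

#' @rdname toy_contigs
#' @return `toy_par_regions()`: PAR mask for the toy chrX (first 50 kb).
#' @export
toy_par_regions <- function() {
  tibble::tibble(chrom = "chrX", start = 1L, end = 50000L)
}

#' @rdname toy_contigs
#' @param ... Overrides passed to [filter_config()].
#' @return `toy_filter_config()`: a [filter_config()] with the toy PAR
#'   masks.
#' @export
toy_filter_config <- function(...) {
  filter_config(par_regions = toy_par_regions(), ...)
}

#' Synthetic gene model for the toy genome
#'
#' 30 genes per autosome and 10 on chrX (outside the toy PAR), 10 kb each,
#' deterministically placed. Symbols are `SYG<contig>_<n>`.
#'
#' @return Tibble `gene`/`chrom`/`start`/`end`/`moi` (moi `"unknown"`).
#' @export
synthetic_gene_table <- function() {
  mk <- function(chrom, tag, n, start0, spacing) {
    start <- start0 + (seq_len(n) - 1L) * spacing
    tibble::tibble(
      gene = sprintf("SYG%s_%02d", tag, seq_len(n)),
      chrom = chrom, start = start, end = start + 9999L, moi = "unknown"
    )
  }
  dplyr::bind_rows(
    mk("chr1", "1", 30L, 20001L, 30000L),
    mk("chr2", "2", 30L, 20001L, 30000L),
    mk("chr7", "7", 30L, 20001L, 30000L),
    mk("chrX", "X", 10L, 100001L, 50000L)
  )
}

gene_at_position <- function(chrom, pos, gene_table = synthetic_gene_table()) {
  out <- rep("", length(chrom))
  for (i in seq_len(nrow(gene_table))) {
    hit <- chrom == gene_table$chrom[i] & pos >= gene_table$start[i] &
      pos <= gene_table$end[i]
    out[hit] <- gene_table$gene[i]
  }
  out
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Per-trio seed derived from the cohort seed; kept below 2^31.
derive_seed <- function(seed, i) {
  (as.double(seed) * 1009 + i * 9973) %% 2147483647
}

#' Trio simulation design entry
#'
#' One entry of a cohort design: which (if any) causal variant to plant,
#' under which inheritance model, in which panel tier, plus the background
#' load.
#'
#' @param trio_id Identifier, used for file naming and sample ids.
#' @param model `"none"` or one of the four inheritance models to plant.
#' @param panel_tier Where the causal gene is discoverable: `"I"` (in the
#'   patient's bespoke phase I panel), `"II"` (disease-gene panels only)
#'   or `"none"` (genome-wide phase III only).
#' @param known_pathogenic Plant carries a curated-pathogenic assertion
#'   (drives the reportable flag downstream).
#' @param permissive_path Plant one allele in the permissive frequency
#'   stratum (5-10% with zero ExAC homozygotes/hemizygotes) instead of the
#'   standard rare stratum.
#' @param secondary_plant Additionally plant a homozygous
#'   recessive variant in a medically actionable (ACMG-like) gene that is
#'   outside all primary panels.
#' @param proband_sex Proband sex; `x_linked` plants force `"male"`.
#' @param n_background Number of Mendelian-consistent background variants,
#'   each constructed to fail at least one filter deterministically.
#' @return A `trio_design` list.
#' @export
trio_design <- function(trio_id,
                        model = c("none", "de_novo", "ar_homozygous",
                                  "ar_compound_het", "x_linked"),
                        panel_tier = c("I", "II", "none"),
                        known_pathogenic = TRUE,
                        permissive_path = FALSE,
                        secondary_plant = FALSE,
                        proband_sex = c("male", "female"),
                        n_background = 2000L) {
  model <- match.arg(model)
  panel_tier <- match.arg(panel_tier)
  proband_sex <- match.arg(proband_sex)
  if (model == "x_linked") proband_sex <- "male"
  structure(
    list(trio_id = trio_id, model = model, panel_tier = panel_tier,
         known_pathogenic = isTRUE(known_pathogenic),
         permissive_path = isTRUE(permissive_path),
         secondary_plant = isTRUE(secondary_plant),
         proband_sex = proband_sex,
         n_background = as.integer(n_background)),
    class = "trio_design"
  )
}

#' Draw population-database annotations for a frequency stratum
#'
#' Three population allele frequencies are drawn independently per
#' database within the stratum (their realistic joint distribution is
#' unknowable; independence is a declared simplification) on a 1e-4 grid
#' so that VCF round-trips are exact.
#'
#' * `rare`: each database absent with probability 0.3, otherwise
#'   frequency at or below 0.5%; no homozygotes/hemizygotes reported.
#' * `permissive`: ExAC frequency 5-10%, others at or below 10% or
#'   absent; zero ExAC homozygotes and hemizygotes.
#' * `common`: all three databases report 2-30%; at least one ExAC
#'   homozygote, so both frequency paths fail deterministically.
#'
#' @param n Number of variants.
#' @param stratum `"rare"`, `"permissive"` or `"common"`.
#' @return Tibble with columns `af_1000g`, `af_exac`, `af_evs`,
#'   `exac_hom_count`, `exac_hemi_count`.
#' @export
write_annotations <- function(n, stratum = c("rare", "permissive", "common")) {
  stratum <- match.arg(stratum)
  grid_af <- function(lo, hi) sample(seq(lo, hi), n, replace = TRUE) / 10000
  maybe_absent <- function(x, p = 0.3) {
    x[stats::runif(n) < p] <- NA_real_
    x
  }
  switch(stratum,
    rare = tibble::tibble(
      af_1000g = maybe_absent(grid_af(0, 50)),
      af_exac = maybe_absent(grid_af(0, 50)),
      af_evs = maybe_absent(grid_af(0, 50)),
      exac_hom_count = ifelse(stats::runif(n) < 0.5, 0L, NA_integer_),
      exac_hemi_count = ifelse(stats::runif(n) < 0.5, 0L, NA_integer_)
    ),
    permissive = tibble::tibble(
      af_1000g = maybe_absent(grid_af(100, 1000)),
      af_exac = grid_af(500, 1000),
      af_evs = maybe_absent(grid_af(100, 1000)),
      exac_hom_count = rep(0L, n),
      exac_hemi_count = rep(0L, n)
    ),
    common = tibble::tibble(
      af_1000g = grid_af(200, 3000),
      af_exac = grid_af(200, 3000),
      af_evs = grid_af(200, 3000),
      exac_hom_count = sample(1:50, n, replace = TRUE),
      exac_hemi_count = sample(0:5, n, replace = TRUE)
    )
  )
}

BASES <- c("A", "C", "G", "T")

sample_alleles <- function(n, consequence) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
                USE.NAMES = FALSE)
  ins <- consequence == "frameshift"
  alt[ins] <- paste0(ref[ins], alt[ins])  # 1-bp insertion
  list(ref = ref, alt = alt)
}

# Mendelian-consistent inherited genotypes. kind:
#   "transmit" - sample parents, transmit alleles (any consistent config)
#   "inert"    - configurations that can never produce a model call or a
#                compound-het arm (proband hom_ref, or het/het/het)
sample_background_genotypes <- function(chrom, pos, proband_sex, kind, cfg) {
  n <- length(chrom)
  hemi <- is_hemizygous_region(chrom, pos, cfg)
  male <- proband_sex == "male"
  mo <- sample(c("hom_ref", "het", "hom_alt"), n, replace = TRUE,
               prob = c(0.55, 0.35, 0.10))
  fa <- ifelse(hemi,
               sample(c("hom_ref", "hemi_alt"), n, replace = TRUE,
                      prob = c(0.7, 0.3)),
               sample(c("hom_ref", "het", "hom_alt"), n, replace = TRUE,
                      prob = c(0.55, 0.35, 0.10)))
  transmit <- function(gt) {
    ifelse(gt %in% c("hom_alt", "hemi_alt"), 1L,
           ifelse(gt == "het", sample(0:1, n, replace = TRUE), 0L))
  }
  m_allele <- transmit(mo)
  f_allele <- transmit(fa)
  pro <- ifelse(m_allele + f_allele == 2L, "hom_alt",
                ifelse(m_allele + f_allele == 1L, "het", "hom_ref"))
  if (male) {
    pro[hemi] <- ifelse(m_allele[hemi] == 1L, "hemi_alt", "hom_ref")
  }
  if (kind == "inert") {
    # het/het/het on autosomes (phase-unresolved), proband hom_ref on X
    use_hhh <- !hemi & stats::runif(n) < 0.5
    pro[use_hhh] <- "het"; mo[use_hhh] <- "het"; fa[use_hhh] <- "het"
    force_ref <- !use_hhh
    pro[force_ref] <- "hom_ref"
    mo[force_ref] <- sample(c("hom_ref", "het"), sum(force_ref),
                            replace = TRUE)
    fa[force_ref & hemi] <- "hom_ref"
    fa[force_ref & !hemi] <- sample(c("hom_ref", "het"),
                                    sum(force_ref & !hemi), replace = TRUE)
    if (!male) {
      # female proband: keep X inert rows proband hom_ref as well
      pro[hemi] <- "hom_ref"
      mo[hemi] <- sample(c("hom_ref", "het"), sum(hemi), replace = TRUE)
      fa[hemi] <- "hom_ref"
    }
  }
  tibble::tibble(proband_gt = pro, mother_gt = mo, father_gt = fa)
}

new_variant_rows <- function(n) {
  tibble::tibble(
    chrom = character(n), pos = integer(n), ref = character(n),
    alt = character(n), gene = character(n), consequence = character(n),
    splice_distance = rep(NA_integer_, n),
    af_1000g = rep(NA_real_, n), af_exac = rep(NA_real_, n),
    af_evs = rep(NA_real_, n),
    exac_hom_count = rep(NA_integer_, n),
    exac_hemi_count = rep(NA_integer_, n),
    known_pathogenic = rep(FALSE, n),
    proband_gt = character(n), mother_gt = character(n),
    father_gt = character(n),
    gq_proband = integer(n), gq_mother = integer(n), gq_father = integer(n),
    dp_proband = integer(n), dp_mother = integer(n), dp_father = integer(n),
    extra_alt = rep(NA_character_, n)
  )
}

finish_quality <- function(v, lo_gq = 30L, hi_gq = 99L, lo_dp = 15L,
                           hi_dp = 60L) {
  n <- nrow(v)
  for (col in c("gq_proband", "gq_mother", "gq_father")) {
    v[[col]] <- sample(lo_gq:hi_gq, n, replace = TRUE)
  }
  for (col in c("dp_proband", "dp_mother", "dp_father")) {
    v[[col]] <- sample(lo_dp:hi_dp, n, replace = TRUE)
  }
  v
}

DELETERIOUS_PLANT_CSQ <- c("stop_gained", "frameshift",
                           "snv_deleterious_missense", "start_lost")

# Build the planted causal variant rows for one design entry.
plant_variants <- function(design, gene_row, cfg) {
  model <- design$model
  n_var <- if (model == "ar_compound_het") 2L else 1L
  v <- new_variant_rows(n_var)
  pos <- sort(sample(seq(gene_row$start, gene_row$end), n_var))
  v$chrom <- gene_row$chrom
  v$pos <- as.integer(pos)
  v$gene <- gene_row$gene
  v$consequence <- sample(DELETERIOUS_PLANT_CSQ, n_var, replace = TRUE)
  alleles <- sample_alleles(n_var, v$consequence)
  v$ref <- alleles$ref
  v$alt <- alleles$alt
  strata <- rep("rare", n_var)
  if (design$permissive_path) strata[1] <- "permissive"
  for (s in unique(strata)) {
    idx <- strata == s
    ann <- write_annotations(sum(idx), s)
    v[idx, names(ann)] <- ann
  }
  v$known_pathogenic <- design$known_pathogenic
  gts <- switch(model,
    de_novo = list(c("het"), c("hom_ref"), c("hom_ref")),
    ar_homozygous = list(c("hom_alt"), c("het"), c("het")),
    ar_compound_het = list(c("het", "het"), c("het", "hom_ref"),
                           c("hom_ref", "het")),
    x_linked = list(c("hemi_alt"), c("het"), c("hom_ref"))
  )
  v$proband_gt <- gts[[1]]
  v$mother_gt <- gts[[2]]
  v$father_gt <- gts[[3]]
  finish_quality(v, lo_gq = 60L, lo_dp = 25L)
}

# Background variants: every one fails >= 1 filter deterministically.
background_variants <- function(n, proband_sex, excluded_genes, cfg,
                                gene_table = synthetic_gene_table(),
                                contigs = toy_contigs()) {
  # oversample positions, drop those landing in excluded genes, keep n
  k <- ceiling(n * 1.6) + 50L
  chrom <- sample(contigs$chrom, k, replace = TRUE,
                  prob = c(0.3, 0.3, 0.3, 0.1))
  pos <- integer(k)
  for (cc in unique(chrom)) {
    idx <- chrom == cc
    len <- contigs$length[contigs$chrom == cc]
    pos[idx] <- sample.int(len, sum(idx), replace = FALSE)
  }
  gene <- gene_at_position(chrom, pos, gene_table)
  keep <- !(toupper(gene) %in% toupper(excluded_genes))
  keep <- keep & !duplicated(paste(chrom, pos))
  if (sum(keep) < n) {
    stop("background oversampling exhausted; lower n_background",
         call. = FALSE)
  }
  chrom <- chrom[keep][seq_len(n)]
  pos <- pos[keep][seq_len(n)]
  gene <- gene[keep][seq_len(n)]

  v <- new_variant_rows(n)
  v$chrom <- chrom
  v$pos <- pos
  v$gene <- gene
  stratum <- sample(c("common", "benign", "inert"), n, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
  # consequences: common stratum may look deleterious (frequency kills it),
  # benign stratum is non-deleterious by category or splice distance,
  # inert stratum is deleterious and rare but its genotypes carry no model
  csq <- character(n)
  csq[stratum == "common"] <- sample(
    c(DELETERIOUS_PLANT_CSQ, "synonymous", "intronic"),
    sum(stratum == "common"), replace = TRUE)
  csq[stratum == "benign"] <- sample(
    c("synonymous", "intronic", "other", "splice_region"),
    sum(stratum == "benign"), replace = TRUE)
  csq[stratum == "inert"] <- sample(
    DELETERIOUS_PLANT_CSQ, sum(stratum == "inert"), replace = TRUE)
  csq[gene == ""] <- "intergenic"
  v$consequence <- csq
  # splice_region rows in the benign stratum sit outside the +/-7 window
  spl <- v$consequence == "splice_region"
  v$splice_distance[spl] <- sample(8:50, sum(spl), replace = TRUE)
  alleles <- sample_alleles(n, v$consequence)
  v$ref <- alleles$ref
  v$alt <- alleles$alt
  ann_stratum <- ifelse(stratum == "common", "common", "rare")
  for (s in c("common", "rare")) {
    idx <- ann_stratum == s
    if (any(idx)) {
      ann <- write_annotations(sum(idx), s)
      v[idx, names(ann)] <- ann
    }
  }
  gt_kind <- ifelse(stratum == "inert", "inert", "transmit")
  for (kind in c("inert", "transmit")) {
    idx <- gt_kind == kind
    if (!any(idx)) next
    g <- sample_background_genotypes(v$chrom[idx], v$pos[idx], proband_sex,
                                     kind, cfg)
    v$proband_gt[idx] <- g$proband_gt
    v$mother_gt[idx] <- g$mother_gt
    v$father_gt[idx] <- g$father_gt
  }
  # the deleterious+rare stratum must never present a callable or
  # phaseable genotype pattern; the other strata fail frequency or
  # consequence filters by construction
  v <- finish_quality(v)
  # a few multiallelic benign records exercise decomposition end-to-end
  cand <- which(stratum == "benign" & v$consequence != "frameshift" &
                  nchar(v$alt) == 1L)
  if (length(cand) >= 3L) {
    pick <- cand[seq_len(3L)]
    v$extra_alt[pick] <- vapply(seq_along(pick), function(i) {
      sample(setdiff(BASES, c(v$ref[pick[i]], v$alt[pick[i]])), 1)
    }, character(1))
  }
  v
}

#' Generate one annotated synthetic trio
#'
#' Produces a Mendelian-consistent annotated trio VCF plus PED file for
#' one [trio_design()] entry: optional planted causal variant(s)
#' satisfying exactly one inheritance model and the frequency/consequence
#' filters, an optional secondary-findings plant, and a background of
#' variants each of which deterministically fails at least one filter
#' (common frequency with reported ExAC homozygotes, benign consequence,
#' or a rare deleterious variant whose inherited genotypes fit no model).
#' Identical seeds produce byte-identical output.
#'
#' @param design A [trio_design()].
#' @param dir Output directory for this trio (created if needed).
#' @param seed Integer seed; fully determines the output.
#' @param causal_gene Row of [synthetic_gene_table()] to host the plant
#'   (chosen by [generate_cohort()]); `NULL` when `model = "none"`.
#' @param secondary_gene Gene row for the secondary plant, when designed.
#' @param cfg A [filter_config()] (use [toy_filter_config()]).
#' @return Invisibly, the truth record: a list with the planted variant
#'   keys, model, genotype configuration and expected discovery phase.
#' @export
generate_trio <- function(design, dir, seed, causal_gene = NULL,
                          secondary_gene = NULL,
                          cfg = toy_filter_config()) {
  stopifnot(inherits(design, "trio_design"))
  if (design$model != "none" && is.null(causal_gene)) {
    stop("design error: model '", design$model, "' needs a causal gene",
         call. = FALSE)
  }
  if (design$model == "ar_compound_het" && !is.null(causal_gene) &&
        (causal_gene$end - causal_gene$start) < 1L) {
    stop("design error: compound het plant needs >= 2 sites in the gene",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tid <- design$trio_id
  ped <- pedigree(tid, paste0(tid, "_P"), paste0(tid, "_M"),
                  paste0(tid, "_F"), design$proband_sex)
  with_seed(seed, {
    parts <- list()
    truth_keys <- character()
    if (design$model != "none") {
      pv <- plant_variants(design, causal_gene, cfg)
      truth_keys <- paste(pv$chrom, pv$pos, pv$ref, pv$alt, sep = ":")
      parts$plant <- pv
    }
    sec_keys <- character()
    if (design$secondary_plant) {
      stopifnot(!is.null(secondary_gene))
      sec_design <- design
      sec_design$model <- "ar_homozygous"
      sec_design$permissive_path <- FALSE
      sec_design$known_pathogenic <- TRUE
      sv <- plant_variants(sec_design, secondary_gene, cfg)
      sec_keys <- paste(sv$chrom, sv$pos, sv$ref, sv$alt, sep = ":")
      parts$secondary <- sv
    }
    excluded <- c(if (!is.null(causal_gene)) causal_gene$gene,
                  if (!is.null(secondary_gene)) secondary_gene$gene)
    parts$background <- background_variants(
      design$n_background, design$proband_sex, excluded, cfg
    )
    v <- dplyr::bind_rows(parts)
    write_trio_vcf(v, ped, file.path(dir, "trio.vcf"),
                   contigs = toy_contigs(), cfg = cfg)
    write_pedigree(ped, file.path(dir, "trio.ped"))
    truth <- list(
      trio_id = tid,
      proband_id = ped$proband_id,
      proband_sex = design$proband_sex,
      model = design$model,
      panel_tier = design$panel_tier,
      causal_gene = if (is.null(causal_gene)) NA else causal_gene$gene,
      variant_keys = as.list(truth_keys),
      known_pathogenic = design$known_pathogenic,
      permissive_path = design$permissive_path,
      secondary = design$secondary_plant,
      secondary_gene = if (is.null(secondary_gene)) NA else
        secondary_gene$gene,
      secondary_keys = as.list(sec_keys),
      expected_phase = if (design$model == "none") NA else
        switch(design$panel_tier, I = "I", II = "II", "III"),
      n_background = design$n_background
    )
    invisible(truth)
  })
}

NOISE_PANEL_GENES <- sprintf("SYG2_%02d", 20:29)
SECONDARY_GENE <- "SYG7_15"
ACMG_TABLE <- function() {
  tibble::tibble(gene = c(SECONDARY_GENE, "SYG7_20", "SYGX_05"),
                 moi = c("recessive", "dominant", "x_linked"))
}

#' Generate a cohort of synthetic trios with shared panel resources
#'
#' Writes one subdirectory per trio (VCF, PED, patient HPO terms,
#' clinician gene list) plus the shared resources the phased pipeline
#' consumes: the HPO term-to-gene map (each trio's terms map to its causal
#' gene when its panel tier is I, plus noise genes), the phase II gene
#' lists (DDG2P-like: chr1 genes plus tier-II causal genes;
#' OMIM-morbid-like: chr2 genes), the actionable-gene list for the
#' secondary scan, the filter configuration (toy PAR masks) and a
#' `manifest.json` of per-trio ground truth. The manifest is the only
#' ground-truth channel: the VCFs carry nothing a real annotator would
#' not supply.
#'
#' @param designs List of [trio_design()] entries.
#' @param dir Output cohort directory.
#' @param seed Integer seed; per-trio seeds are derived from it and the
#'   output is byte-identical across runs with the same seed.
#' @return Invisibly, the manifest list.
#' @export
generate_cohort <- function(designs, dir, seed) {
  stopifnot(length(designs) >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- synthetic_gene_table()
  cfg <- toy_filter_config()
  acmg <- ACMG_TABLE()

  # deterministic causal-gene assignment: autosomal plants walk chr1
  # genes, X-linked plants walk chrX genes
  auto_pool <- gt[gt$chrom == "chr1", ]
  x_pool <- gt[gt$chrom == "chrX" & !gt$gene %in% acmg$gene, ]
  auto_i <- 0L; x_i <- 0L
  truths <- list()
  hpo_rows <- list()
  term_no <- 100L
  moi_for_model <- function(model) {
    switch(model, de_novo = "dominant", ar_homozygous = "recessive",
           ar_compound_het = "recessive", x_linked = "x_linked", "unknown")
  }
  for (k in seq_along(designs)) {
    d <- designs[[k]]
    causal <- NULL
    if (d$model %in% c("de_novo", "ar_homozygous", "ar_compound_het")) {
      auto_i <- auto_i + 1L
      causal <- auto_pool[((auto_i - 1L) %% nrow(auto_pool)) + 1L, ]
    } else if (d$model == "x_linked") {
      x_i <- x_i + 1L
      causal <- x_pool[((x_i - 1L) %% nrow(x_pool)) + 1L, ]
    }
    secondary <- if (d$secondary_plant) gt[gt$gene == SECONDARY_GENE, ]
                 else NULL
    truth <- generate_trio(d, file.path(dir, d$trio_id),
                           derive_seed(seed, k), causal, secondary, cfg)
    truths[[k]] <- truth
    # per-trio HPO terms: one patient-specific term, one shared noise term
    term <- sprintf("HP:%07d", term_no + k)
    terms <- c(term, "HP:0000001")
    writeLines(terms, file.path(dir, d$trio_id, "hpo_terms.txt"))
    noise <- NOISE_PANEL_GENES[(k %% length(NOISE_PANEL_GENES)) + 1L]
    rows <- tibble::tibble(term = term, gene = noise, moi = "unknown")
    if (!is.null(causal) && d$panel_tier == "I") {
      rows <- dplyr::bind_rows(
        tibble::tibble(term = term, gene = causal$gene,
                       moi = moi_for_model(d$model)),
        rows
      )
    }
    hpo_rows[[k]] <- rows
    # clinician list: a fixed pair of panel genes; for one trio in three
    # the causal gene is also clinician-supplied (dual provenance)
    clin <- c("SYG2_25", "SYG2_26")
    if (!is.null(causal) && d$panel_tier == "I" && k %% 3L == 1L) {
      clin <- c(clin, causal$gene)
    }
    writeLines(clin, file.path(dir, d$trio_id, "clinician_genes.txt"))
  }
  hpo_map <- dplyr::bind_rows(
    dplyr::bind_rows(hpo_rows),
    tibble::tibble(term = "HP:0000001", gene = "SYG2_28", moi = "unknown")
  )
  utils::write.table(hpo_map, file.path(dir, "hpo_gene_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  tier2_genes <- unlist(lapply(seq_along(designs), function(k) {
    if (designs[[k]]$panel_tier == "II" && !is.na(truths[[k]]$causal_gene))
      truths[[k]]$causal_gene
  }))
  ddg2p <- sort(unique(c(gt$gene[gt$chrom == "chr1"], tier2_genes)))
  omim <- gt$gene[gt$chrom == "chr2"]
  writeLines(ddg2p, file.path(dir, "ddg2p.tsv"))
  writeLines(omim, file.path(dir, "omim_morbid.tsv"))
  utils::write.table(acmg, file.path(dir, "acmg_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_filter_config(cfg, file.path(dir, "config.json"))
  manifest <- list(seed = seed, n_trios = length(designs), trios = truths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(manifest)
}

#' Generate the standard 24-trio fixture cohort
#'
#' The fixture mirrors the composition of the study cohort this workflow
#' is validated against: 24 trios of which 10 carry a reportable primary
#' plant in a phase I panel gene -- 4 de novo, 3 compound-heterozygous
#' pairs (one pair exercising the permissive 5-10% frequency stratum) and
#' 3 recessive homozygotes -- plus 1 trio carrying only a homozygous
#' secondary-findings plant in an actionable gene outside all primary
#' panels, and 13 background-only trios. Every background variant fails at
#' least one filter deterministically, so the 14 trios without a primary
#' plant must report no primary findings.
#'
#' @param dir Output directory.
#' @param seed Integer seed (fully determines the cohort).
#' @param n_background Background variants per trio (default 2000 on the
#'   toy 4-contig genome).
#' @return Invisibly, the manifest list (see [generate_cohort()]).
#' @export
generate_fixture_cohort <- function(dir, seed, n_background = 2000L) {
  mk <- function(i, ...) {
    trio_design(sprintf("trio_%02d", i),
                proband_sex = if (i %% 2L == 0L) "female" else "male",
                n_background = n_background, ...)
  }
  designs <- c(
    lapply(1:4, function(i) mk(i, model = "de_novo")),
    lapply(5:7, function(i) mk(i, model = "ar_compound_het",
                               permissive_path = (i == 5L))),
    lapply(8:10, function(i) mk(i, model = "ar_homozygous")),
    list(mk(11L, model = "none", secondary_plant = TRUE)),
    lapply(12:24, function(i) mk(i, model = "none"))
  )
  generate_cohort(designs, dir, seed)
}
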