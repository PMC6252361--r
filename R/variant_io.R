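CANONICAL_CONTIG_CORES <- c(as.character(1:22), "X", "Y", "M")

#' Normalize chromosome labels to the "chr"-prefixed dialect
#'
#' `"X"` becomes `"chrX"`, `"chr7"` stays `"chr7"`, `"MT"`/`"chrMT"` become
#' `"chrM"`. Labels outside the canonical contig alphabet (e.g. unplaced
#' scaffolds such as `"GL000220.1"`) are preserved verbatim; use
#' [is_canonical_chrom()] to flag them.
#'
#' @param label Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(label) {
  core <- sub("^chr", "", label, ignore.case = TRUE)
  core <- ifelse(toupper(core) %in% c("X", "Y"), toupper(core), core)
  core <- ifelse(toupper(core) %in% c("M", "MT"), "M", core)
  ifelse(core %in% CANONICAL_CONTIG_CORES, paste0("chr", core), label)
}

#' @rdname normalize_chrom
#' @return `is_canonical_chrom()`: logical vector, `FALSE` for contigs
#'   outside the canonical alphabet.
#' @export
is_canonical_chrom <- function(label) {
  normalize_chrom(label) %in% paste0("chr", CANONICAL_CONTIG_CORES)
}

# Recode one GT string with respect to alt allele `allele_index`:
# that allele becomes 1, every other allele (including other alts) 0,
# missing alleles stay ".". Separators are normalized to "/".
recode_gt_for_allele <- function(gt, allele_index) {
  vapply(gt, function(g) {
    parts <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1]]
    coded <- ifelse(parts == ".", ".",
                    ifelse(parts == as.character(allele_index), "1", "0"))
    # unphased convention: report alleles in sorted order (ref first)
    if (!any(coded == ".")) coded <- sort(coded)
    paste(coded, collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

is_symbolic_alt <- function(alt) {
  grepl("^<.+>$", alt) | alt == "*" | grepl("[][]", alt)
}

#' Decompose multiallelic records into biallelic variants
#'
#' Splits each raw record with k alt alleles into k biallelic records so
#' that per-variant frequency, consequence and inheritance filters are
#' well defined. Genotypes are recoded per alt allele, other alt alleles
#' being treated as reference for that record; all records arising from a
#' multiallelic site are flagged `from_multiallelic`. Symbolic alts
#' (`<DEL>` and friends) are passed through as single records flagged
#' `symbolic` and are excluded from downstream filters.
#'
#' @param raw A data frame of raw records with columns `chrom`, `pos`,
#'   `ref`, a list-column `alts` (character vector of alt alleles per
#'   record), the raw GT string columns `gt_proband`, `gt_mother`,
#'   `gt_father`, and any per-record annotation columns (carried over to
#'   every decomposed record).
#' @return A tibble with one row per alt allele: `alt`, `allele_index`,
#'   `from_multiallelic`, `symbolic`, recoded GT strings, and all other
#'   columns of `raw`.
#' @export
decompose_multiallelic <- function(raw) {
  raw <- tibble::as_tibble(raw)
  stopifnot(all(c("chrom", "pos", "ref", "alts",
                  "gt_proband", "gt_mother", "gt_father") %in% names(raw)))
  n_alts <- lengths(raw$alts)
  stopifnot(all(n_alts >= 1L))
  idx <- rep(seq_len(nrow(raw)), n_alts)
  out <- raw[idx, setdiff(names(raw), "alts")]
  out$alt <- unlist(raw$alts, use.names = FALSE)
  out$allele_index <- unlist(lapply(n_alts, seq_len), use.names = FALSE)
  out$from_multiallelic <- rep(n_alts > 1L, n_alts)
  out$symbolic <- is_symbolic_alt(out$alt)
  multi <- out$from_multiallelic & !out$symbolic
  for (col in c("gt_proband", "gt_mother", "gt_father")) {
    gt <- out[[col]]
    gt[multi] <- unlist(Map(recode_gt_for_allele, gt[multi],
                            out$allele_index[multi]), use.names = FALSE)
    # biallelic records keep their GT verbatim apart from separator cleanup
    gt[!multi & !out$symbolic] <-
      recode_gt_for_allele(gt[!multi & !out$symbolic], 1L)
    out[[col]] <- gt
  }
  tibble::as_tibble(out)
}

# Pull one INFO column (or NA of the right type) from a readVcf object.
info_column <- function(vcf, key, type = c("numeric", "integer", "character",
                                           "logical")) {
  type <- match.arg(type)
  info_df <- VariantAnnotation::info(vcf)
  n <- nrow(info_df)
  if (is.null(key) || !key %in% names(info_df)) {
    return(switch(type,
                  numeric = rep(NA_real_, n),
                  integer = rep(NA_integer_, n),
                  character = rep(NA_character_, n),
                  logical = rep(FALSE, n)))
  }
  col <- info_df[[key]]
  if (is(col, "List") || is.list(col)) {
    col <- vapply(as.list(col), function(x) {
      if (length(x) == 0) NA else x[[1]]
    }, vector(mode = if (type == "logical") "logical" else type, 1))
  }
  if (type %in% c("numeric", "integer") && is.character(col)) {
    conv <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "." & is.na(conv))
    if (length(bad)) {
      stop("malformed value for INFO key '", key, "' at record(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    col <- conv
  }
  switch(type,
         numeric = as.numeric(col),
         integer = as.integer(col),
         character = as.character(col),
         logical = {col[is.na(col)] <- FALSE; as.logical(col)})
}

#' Read an annotated trio VCF into the pipeline data model
#'
#' Parses a multi-sample VCF (plain or bgzipped) with
#' `VariantAnnotation::readVcf()`, decomposes multiallelic records,
#' normalizes chromosome labels, encodes trio genotypes into the
#' five-state model and applies the genotype-quality gate (GQ and depth in
#' all three samples, thresholds from `cfg`; records failing the gate are
#' dropped and counted in the `n_qc_dropped` attribute). Missing
#' annotations map to `NA` ("absent"), never silently to 0: an unreported
#' population frequency means the variant was not observed there.
#'
#' @param path Path to a VCF file containing the three pedigree samples.
#' @param ped A [pedigree()].
#' @param cfg A [filter_config()]; `cfg$field_map` names the INFO keys
#'   carrying the annotations.
#' @return A tibble of annotated biallelic variants in contig order, one
#'   row per variant, with genotype states `proband_gt`, `mother_gt`,
#'   `father_gt` and a `variant_id` key (`chrom:pos:ref:alt`).
#' @export
read_trio_vcf <- function(path, ped, cfg = filter_config()) {
  stopifnot(inherits(ped, "pedigree"))
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  samples <- colnames(vcf)
  needed <- c(ped$proband_id, ped$mother_id, ped$father_id)
  absent <- setdiff(needed, samples)
  if (length(absent)) {
    stop("sample not found in VCF: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_l <- VariantAnnotation::alt(vcf)
  alts <- lapply(seq_along(alt_l), function(i) as.character(alt_l[[i]]))
  gt <- VariantAnnotation::geno(vcf)$GT
  geno_fields <- VariantAnnotation::geno(vcf)
  gq <- if ("GQ" %in% names(geno_fields)) geno_fields$GQ else NULL
  dp <- if ("DP" %in% names(geno_fields)) geno_fields$DP else NULL
  fm <- cfg$field_map
  raw <- tibble::tibble(
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(rr))),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alts = alts,
    gene = info_column(vcf, fm$gene, "character"),
    consequence = info_column(vcf, fm$consequence, "character"),
    splice_distance = info_column(vcf, fm$splice_distance, "integer"),
    af_1000g = info_column(vcf, fm$af_1000g, "numeric"),
    af_exac = info_column(vcf, fm$af_exac, "numeric"),
    af_evs = info_column(vcf, fm$af_evs, "numeric"),
    exac_hom_count = info_column(vcf, fm$exac_hom_count, "integer"),
    exac_hemi_count = info_column(vcf, fm$exac_hemi_count, "integer"),
    known_pathogenic = info_column(vcf, fm$known_pathogenic, "logical"),
    gt_proband = unname(gt[, ped$proband_id]),
    gt_mother = unname(gt[, ped$mother_id]),
    gt_father = unname(gt[, ped$father_id])
  )
  for (role in c("proband", "mother", "father")) {
    id <- ped[[paste0(role, "_id")]]
    raw[[paste0("gq_", role)]] <-
      if (is.null(gq)) NA_integer_ else as.integer(gq[, id])
    raw[[paste0("dp_", role)]] <-
      if (is.null(dp)) NA_integer_ else as.integer(dp[, id])
  }
  v <- decompose_multiallelic(raw)
  v$gene[is.na(v$gene) | v$gene == "."] <- ""
  v$consequence[is.na(v$consequence)] <- "other"
  bad_csq <- !v$consequence %in% CONSEQUENCE_CATEGORIES
  v$consequence[bad_csq] <- "other"
  # genotype quality gate across all three samples (NA = field absent,
  # which passes: the gate only acts on reported quality values)
  gq_ok <- function(x) is.na(x) | x >= cfg$min_gq
  dp_ok <- function(x) is.na(x) | x >= cfg$min_dp
  pass_qc <- gq_ok(v$gq_proband) & gq_ok(v$gq_mother) & gq_ok(v$gq_father) &
    dp_ok(v$dp_proband) & dp_ok(v$dp_mother) & dp_ok(v$dp_father)
  n_dropped <- sum(!pass_qc)
  v <- v[pass_qc, , drop = FALSE]
  sexes <- c(proband = ped$proband_sex, mother = "female", father = "male")
  for (role in names(sexes)) {
    v[[paste0(role, "_gt")]] <- encode_genotypes(
      v[[paste0("gt_", role)]], sexes[[role]], v$chrom, v$pos, cfg
    )
  }
  v$chrom_canonical <- is_canonical_chrom(v$chrom)
  v$variant_id <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  afs <- cbind(v$af_1000g, v$af_exac, v$af_evs)
  v$max_af <- apply(afs, 1, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  contig_order <- unique(v$chrom)
  v <- v[order(match(v$chrom, contig_order), v$pos, v$alt), , drop = FALSE]
  attr(v, "pedigree") <- ped
  attr(v, "n_qc_dropped") <- n_dropped
  v
}

# Build a VCF INFO string from one variant row's annotation fields.
build_info_string <- function(v, fm) {
  fmt_num <- function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
  }
  pieces <- list(
    gene = ifelse(is.na(v$gene) | v$gene == "", NA_character_,
                  paste0(fm$gene, "=", v$gene)),
    csq = ifelse(is.na(v$consequence), NA_character_,
                 paste0(fm$consequence, "=", v$consequence)),
    spl = ifelse(is.na(v$splice_distance), NA_character_,
                 paste0(fm$splice_distance, "=", v$splice_distance)),
    a1 = ifelse(is.na(v$af_1000g), NA_character_,
                paste0(fm$af_1000g, "=", fmt_num(v$af_1000g))),
    a2 = ifelse(is.na(v$af_exac), NA_character_,
                paste0(fm$af_exac, "=", fmt_num(v$af_exac))),
    a3 = ifelse(is.na(v$af_evs), NA_character_,
                paste0(fm$af_evs, "=", fmt_num(v$af_evs))),
    hom = ifelse(is.na(v$exac_hom_count), NA_character_,
                 paste0(fm$exac_hom_count, "=", v$exac_hom_count)),
    hemi = ifelse(is.na(v$exac_hemi_count), NA_character_,
                  paste0(fm$exac_hemi_count, "=", v$exac_hemi_count)),
    kp = ifelse(!is.na(v$known_pathogenic) & v$known_pathogenic,
                fm$known_pathogenic, NA_character_)
  )
  mat <- do.call(cbind, pieces)
  apply(mat, 1, function(row) {
    row <- row[!is.na(row)]
    if (!length(row)) "." else paste(row, collapse = ";")
  })
}

vcf_header_lines <- function(contigs, fm, samples) {
  c(
    "##fileformat=VCFv4.2",
    "##source=triotriage",
    sprintf("##contig=<ID=%s,length=%d>", contigs$chrom,
            as.integer(contigs$length)),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">",
            fm$gene),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=String,Description=",
                   "\"Consequence category\">"), fm$consequence),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Integer,Description=",
                   "\"Distance to nearest exon boundary (bp)\">"),
            fm$splice_distance),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,Description=",
                   "\"1000 Genomes allele frequency\">"), fm$af_1000g),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,Description=",
                   "\"ExAC allele frequency\">"), fm$af_exac),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Float,Description=",
                   "\"EVS allele frequency\">"), fm$af_evs),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Integer,Description=",
                   "\"ExAC homozygote count\">"), fm$exac_hom_count),
    sprintf(paste0("##INFO=<ID=%s,Number=1,Type=Integer,Description=",
                   "\"ExAC hemizygote count\">"), fm$exac_hemi_count),
    sprintf(paste0("##INFO=<ID=%s,Number=0,Type=Flag,Description=",
                   "\"Curated pathogenic assertion\">"), fm$known_pathogenic),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
}

#' Write decomposed trio variants back to a multi-sample VCF
#'
#' Emits one biallelic record per variant row with the pipeline's
#' annotation INFO fields and GT:GQ:DP sample columns, suitable for
#' re-reading with [read_trio_vcf()] (round-trip safe). Used by the
#' synthetic cohort generator and for exporting filtered variant sets.
#'
#' @param variants Tibble of variants as produced by [read_trio_vcf()] (or
#'   the synthetic generator); genotype states are re-encoded as GT
#'   strings using each sample's sex and the PAR masks in `cfg`.
#' @param ped A [pedigree()].
#' @param path Output path (`.vcf`).
#' @param contigs Data frame `chrom`/`length` for the header.
#' @param cfg A [filter_config()].
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(variants, ped, path, contigs = toy_contigs(),
                           cfg = filter_config()) {
  v <- tibble::as_tibble(variants)
  v <- v[order(match(v$chrom, contigs$chrom), v$pos, v$alt), , drop = FALSE]
  fm <- cfg$field_map
  sexes <- c(proband = ped$proband_sex, mother = "female", father = "male")
  gts <- lapply(names(sexes), function(role) {
    st <- v[[paste0(role, "_gt")]]
    state_to_gt_string(st, sexes[[role]], v$chrom, v$pos, cfg)
  })
  names(gts) <- names(sexes)
  sample_field <- function(role) {
    gq <- v[[paste0("gq_", role)]]
    dp <- v[[paste0("dp_", role)]]
    if (is.null(gq)) gq <- rep(99L, nrow(v))
    if (is.null(dp)) dp <- rep(30L, nrow(v))
    paste(gts[[role]], ifelse(is.na(gq), ".", gq), ifelse(is.na(dp), ".", dp),
          sep = ":")
  }
  alt_field <- v$alt
  if ("extra_alt" %in% names(v)) {
    multi <- !is.na(v$extra_alt)
    alt_field[multi] <- paste(v$alt[multi], v$extra_alt[multi], sep = ",")
  }
  records <- paste(
    v$chrom, v$pos, ".", v$ref, alt_field, ".", "PASS",
    build_info_string(v, fm), "GT:GQ:DP",
    sample_field("proband"), sample_field("mother"), sample_field("father"),
    sep = "\t"
  )
  header <- vcf_header_lines(
    contigs, fm, c(ped$proband_id, ped$mother_id, ped$father_id)
  )
  writeLines(c(header, records), path)
  invisible(path)
}
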