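PHASES <- c("I", "II", "III")

#' Run one analysis phase over a trio's variants
#'
#' Applies the phase's gene-panel scope, the predicted-deleterious
#' consequence filter and the frequency filters to the decomposed,
#' quality-gated trio variants, then classifies the survivors under the
#' four inheritance models. De novo candidates must pass the standard
#' rare-frequency filter; recessive and X-linked candidates may instead
#' pass the permissive high-carrier-frequency rule. In phase I the lone
#' deleterious heterozygotes in recessive-MOI panel genes are additionally
#' shortlisted for manual structural-variant review.
#'
#' @param variants Tibble from [read_trio_vcf()].
#' @param panel A [gene_panel()] for the phase (universal for phase III).
#' @param phase `"I"`, `"II"` or `"III"`.
#' @param ped A [pedigree()].
#' @param cfg A [filter_config()].
#' @return A `candidate_set`: list with `phase`, `calls` (model-call
#'   tibble with a `reportable` flag), `het_shortlist` (phase I only),
#'   `trail` (per-variant filter trail) and `counts`.
#' @export
run_phase <- function(variants, panel, phase, ped, cfg = filter_config()) {
  phase <- match.arg(phase, PHASES)
  stopifnot(inherits(panel, "gene_panel"), inherits(ped, "pedigree"))
  if (phase %in% c("I", "II") && !panel$universal && !length(panel$genes)) {
    stop("empty panel for phase ", phase, call. = FALSE)
  }
  trail <- filter_trail(variants, cfg, panel)
  base <- trail$in_scope & trail$deleterious & !trail$symbolic
  dn_set <- base & trail$std_freq
  rec_set <- base & (trail$std_freq | trail$perm_freq)
  calls <- dplyr::bind_rows(
    call_de_novo(variants[dn_set, , drop = FALSE]),
    call_ar_homozygous(variants[rec_set, , drop = FALSE], ped, cfg),
    call_compound_het(variants[rec_set, , drop = FALSE], ped, cfg),
    call_x_linked(variants[rec_set, , drop = FALSE], ped, cfg)
  )
  if (nrow(calls)) {
    calls$phase <- phase
    calls$reportable <- calls$known_pathogenic & phase != "III"
    calls$classification <- NA_character_  # ACMG class is assigned at MDT
  } else {
    calls <- empty_calls()
    calls$phase <- character(0)
    calls$reportable <- logical(0)
    calls$classification <- character(0)
  }
  shortlist <- NULL
  if (phase == "I" && !is.null(panel$moi_by_gene)) {
    shortlist <- shortlist_single_hets(
      variants[rec_set, , drop = FALSE], panel$moi_by_gene, ped, cfg
    )
  }
  structure(
    list(
      phase = phase,
      calls = calls,
      het_shortlist = shortlist,
      trail = trail,
      counts = c(
        n_variants = nrow(variants),
        n_in_scope = sum(trail$in_scope),
        n_deleterious = sum(base),
        n_standard_freq = sum(dn_set),
        n_recessive_freq = sum(rec_set),
        n_calls = nrow(calls)
      )
    ),
    class = "candidate_set"
  )
}

#' Phase escalation decision
#'
#' A phase I or II result deemed to fully explain the phenotype stops the
#' analysis; otherwise the next phase runs. Escalation is automatic when a
#' phase produced no reportable calls; with calls present the decision is
#' a clinical judgement supplied as `mdt_decision`. The `"auto"` policy
#' (used for unattended runs) treats any reportable call as fully
#' explaining the phenotype and escalates otherwise.
#'
#' @param phase Phase just completed (`"I"`, `"II"`, `"III"`).
#' @param n_reportable Number of reportable calls the phase produced.
#' @param mdt_decision `"auto"`, `"fully_explained"`, `"partial"` or
#'   `"unexplained"`.
#' @return `"II"`, `"III"` or `"stop"`.
#' @export
escalate <- function(phase, n_reportable,
                     mdt_decision = c("auto", "fully_explained", "partial",
                                      "unexplained")) {
  phase <- match.arg(phase, PHASES)
  mdt_decision <- match.arg(mdt_decision)
  if (n_reportable == 0L) {
    decision <- "unexplained"
  } else if (mdt_decision == "auto") {
    decision <- "fully_explained"
  } else {
    decision <- mdt_decision
  }
  if (decision == "fully_explained" || phase == "III") return("stop")
  switch(phase, I = "II", II = "III")
}

#' Opt-in secondary-findings scan
#'
#' Screens the trio's variants against a medically actionable gene list
#' (ACMG-like, with per-gene mode of inheritance) for deleterious,
#' frequency-passing variants carrying an inheritance-model call
#' consistent with the gene's MOI: recessive genes require a homozygous or
#' compound-heterozygous call, dominant genes a de novo call, X-linked
#' genes an X-linked call. The scan runs only with explicit opt-in consent
#' and only at phase II breadth; variants already reported as primary
#' findings are excluded.
#'
#' @param variants Tibble from [read_trio_vcf()].
#' @param acmg_genes Tibble `gene`/`moi`, see [read_acmg_genes()].
#' @param opt_in Consent flag; `FALSE` returns an empty set unconditionally.
#' @param ped A [pedigree()].
#' @param cfg A [filter_config()].
#' @param exclude_ids Variant ids already reported as primary findings.
#' @return Tibble of secondary-finding model calls.
#' @export
scan_secondary_findings <- function(variants, acmg_genes, opt_in, ped,
                                    cfg = filter_config(),
                                    exclude_ids = character()) {
  if (!isTRUE(opt_in)) return(empty_calls())
  if (!nrow(acmg_genes)) return(empty_calls())
  panel <- gene_panel("secondary_findings", acmg_genes$gene,
                      moi_by_gene = stats::setNames(acmg_genes$moi,
                                                    acmg_genes$gene))
  cs <- run_phase(variants, panel, "II", ped, cfg)
  calls <- cs$calls
  if (!nrow(calls)) return(empty_calls())
  moi <- stats::setNames(acmg_genes$moi, toupper(acmg_genes$gene))
  wanted <- switch_moi_models(moi[toupper(calls$gene)])
  keep <- mapply(function(m, w) m %in% w, calls$model, wanted)
  partner_excluded <- !is.na(calls$partner_id) &
    calls$partner_id %in% exclude_ids
  calls <- calls[keep & !calls$variant_id %in% exclude_ids &
                   !partner_excluded, , drop = FALSE]
  calls$phase <- "II"
  calls
}

# models compatible with each mode of inheritance
switch_moi_models <- function(moi) {
  lapply(moi, function(m) {
    switch(as.character(m),
      recessive = c("ar_homozygous", "ar_compound_het"),
      dominant = "de_novo",
      x_linked = "x_linked",
      c("de_novo", "ar_homozygous", "ar_compound_het", "x_linked")
    )
  })
}

#' Deterministic candidate ranking
#'
#' Total order over model calls: curated known-pathogenic assertions
#' first; then phase (I before II before III); then model priority
#' (de novo, AR homozygous, AR compound het, X-linked); then ascending
#' maximum reported population frequency (absent frequencies rank as
#' rarest); ties broken by genomic coordinate.
#'
#' @param calls Tibble of model calls.
#' @return The same tibble, ordered, with a `rank` column.
#' @export
rank_candidates <- function(calls) {
  if (!nrow(calls)) {
    calls$rank <- integer(0)
    return(calls)
  }
  chrom_rank <- match(calls$chrom, paste0("chr", CANONICAL_CONTIG_CORES))
  chrom_rank[is.na(chrom_rank)] <- length(CANONICAL_CONTIG_CORES) + 1L
  phase <- if ("phase" %in% names(calls)) calls$phase
           else rep("I", nrow(calls))
  ord <- order(
    -as.integer(calls$known_pathogenic),
    match(phase, PHASES),
    match(calls$model, MODEL_LEVELS),
    ifelse(is.na(calls$max_af), -1, calls$max_af),
    chrom_rank,
    calls$pos,
    calls$variant_id
  )
  out <- calls[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a triage report for one trio
#'
#' The outcome is `provisional_finding` when at least one reportable
#' (curated-pathogenic, phase I/II) call survived, otherwise
#' `no_primary_findings`. Phase III candidates are research-only and never
#' diagnostic; secondary findings appear only when consent was opted in.
#'
#' @param patient_id Patient/proband identifier.
#' @param candidate_sets List of `candidate_set` objects (phases run, in
#'   order).
#' @param secondary Tibble of secondary-finding calls (may be empty).
#' @param opt_in Secondary-findings consent flag.
#' @return An object of class `triage_report`.
#' @export
generate_report <- function(patient_id, candidate_sets, secondary = NULL,
                            opt_in = FALSE) {
  stopifnot(length(candidate_sets) >= 1L)
  phases_run <- vapply(candidate_sets, function(cs) cs$phase, character(1))
  all_calls <- dplyr::bind_rows(lapply(candidate_sets, function(cs) cs$calls))
  diagnostic <- all_calls[all_calls$phase %in% c("I", "II") &
                            all_calls$reportable, , drop = FALSE]
  diagnostic <- rank_candidates(diagnostic)
  research <- all_calls[all_calls$phase == "III", , drop = FALSE]
  research <- rank_candidates(research)
  if (is.null(secondary)) secondary <- empty_calls()
  if (!isTRUE(opt_in) && nrow(secondary)) {
    stop("secondary findings present without opt-in consent", call. = FALSE)
  }
  shortlists <- dplyr::bind_rows(
    lapply(candidate_sets, function(cs) cs$het_shortlist)
  )
  outcome <- if (nrow(diagnostic)) "provisional_finding" else
    "no_primary_findings"
  structure(
    list(
      patient_id = patient_id,
      outcome = outcome,
      phases_run = phases_run,
      diagnostic_calls = diagnostic,
      research_candidates = research,
      secondary_findings = secondary,
      het_shortlist = shortlists,
      opt_in_secondary = isTRUE(opt_in),
      filter_counts = lapply(stats::setNames(candidate_sets,
                                             paste0("phase_", phases_run)),
                             function(cs) as.list(cs$counts))
    ),
    class = "triage_report"
  )
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("Triage report for %s: %s\n", x$patient_id, x$outcome))
  cat(sprintf("  phases run: %s\n", paste(x$phases_run, collapse = ", ")))
  cat(sprintf("  diagnostic calls: %d; research candidates: %d; ",
              nrow(x$diagnostic_calls), nrow(x$research_candidates)))
  cat(sprintf("secondary findings: %d\n", nrow(x$secondary_findings)))
  invisible(x)
}

#' Serialize a triage report to JSON and TSV
#'
#' Writes `<patient_id>_report.json` (full report) and
#' `<patient_id>_calls.tsv` (diagnostic calls, research candidates,
#' secondary findings and the het shortlist as one table with a `section`
#' column). Output is deterministic: no timestamps, fixed column order.
#'
#' @param report A [generate_report()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "triage_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, paste0(report$patient_id, "_report.json"))
  tsv_path <- file.path(dir, paste0(report$patient_id, "_calls.tsv"))
  jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  section <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df <- tibble::as_tibble(df)
    df$section <- name
    df
  }
  tab <- dplyr::bind_rows(
    section(report$diagnostic_calls, "diagnostic"),
    section(report$secondary_findings, "secondary"),
    section(report$research_candidates, "research_only"),
    section(report$het_shortlist, "het_shortlist")
  )
  if (is.null(tab) || !nrow(tab)) {
    tab <- tibble::tibble(section = character(), variant_id = character())
  }
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(json = json_path, tsv = tsv_path))
}

#' End-to-end phased triage of one trio
#'
#' Orchestrates the full workflow on one trio: phase I on the bespoke
#' HPO/clinician panel; escalation to phase II (disease-gene panels) when
#' phase I did not fully explain the phenotype, with the opt-in
#' secondary-findings scan at phase II breadth; escalation to the
#' genome-wide phase III research scope when phase II did not either.
#'
#' @param vcf_path Path to the annotated trio VCF (or a variants tibble
#'   from [read_trio_vcf()]).
#' @param ped A [pedigree()].
#' @param phase1_panel,phase2_panel [gene_panel()] objects.
#' @param acmg_genes Tibble `gene`/`moi` for the secondary scan (may be
#'   `NULL` when `opt_in_secondary = FALSE`).
#' @param cfg A [filter_config()].
#' @param opt_in_secondary Secondary-findings consent flag.
#' @param mdt_decision Escalation decision after a phase with calls:
#'   `"auto"`, `"fully_explained"`, `"partial"` or `"unexplained"` (see
#'   [escalate()]).
#' @param out_dir Optional directory; when given the report is serialized
#'   there via [write_report()].
#' @return A `triage_report`.
#' @export
triage_trio <- function(vcf_path, ped, phase1_panel, phase2_panel,
                        acmg_genes = NULL, cfg = filter_config(),
                        opt_in_secondary = FALSE, mdt_decision = "auto",
                        out_dir = NULL) {
  variants <- if (is.character(vcf_path)) {
    read_trio_vcf(vcf_path, ped, cfg)
  } else {
    vcf_path
  }
  sets <- list()
  secondary <- empty_calls()

  cs1 <- run_phase(variants, phase1_panel, "I", ped, cfg)
  sets <- c(sets, list(cs1))
  nxt <- escalate("I", sum(cs1$calls$reportable), mdt_decision)

  if (nxt == "II") {
    cs2 <- run_phase(variants, phase2_panel, "II", ped, cfg)
    sets <- c(sets, list(cs2))
    if (isTRUE(opt_in_secondary) && !is.null(acmg_genes)) {
      primary_ids <- unique(c(cs1$calls$variant_id, cs2$calls$variant_id,
                              cs1$calls$partner_id, cs2$calls$partner_id))
      secondary <- scan_secondary_findings(
        variants, acmg_genes, opt_in_secondary, ped, cfg,
        exclude_ids = primary_ids[!is.na(primary_ids)]
      )
    }
    nxt <- escalate("II", sum(cs2$calls$reportable), mdt_decision)
    if (nxt == "III") {
      cs3 <- run_phase(variants, phase3_scope(), "III", ped, cfg)
      sets <- c(sets, list(cs3))
    }
  }
  report <- generate_report(ped$proband_id, sets, secondary,
                            opt_in = isTRUE(opt_in_secondary))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Triage every trio of a generated cohort directory
#'
#' Convenience driver for cohorts produced by [generate_fixture_cohort()]
#' or [generate_cohort()]: reads the shared panels, maps and configuration
#' from the cohort directory, runs [triage_trio()] on every trio and
#' returns one summary row per trio.
#'
#' @param cohort_dir Cohort directory containing `manifest.json`, shared
#'   panel/map files and one subdirectory per trio.
#' @param opt_in_secondary,mdt_decision Passed to [triage_trio()].
#' @param out_dir Optional directory for serialized reports.
#' @return Tibble with one row per trio: `trio_id`, `outcome`, top call
#'   model/gene, phases run, counts of diagnostic/secondary/research
#'   calls; the full reports in the `report` list-column.
#' @export
triage_cohort <- function(cohort_dir, opt_in_secondary = TRUE,
                          mdt_decision = "auto", out_dir = NULL) {
  manifest_path <- file.path(cohort_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("not a cohort directory (no manifest.json): ", cohort_dir,
         call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  cfg <- read_filter_config(file.path(cohort_dir, "config.json"))
  hpo_map <- read_hpo_map(file.path(cohort_dir, "hpo_gene_map.tsv"))
  ddg2p <- read_gene_list(file.path(cohort_dir, "ddg2p.tsv"))
  omim <- read_gene_list(file.path(cohort_dir, "omim_morbid.tsv"))
  acmg <- read_acmg_genes(file.path(cohort_dir, "acmg_genes.tsv"))
  phase2 <- build_phase2_panel(ddg2p, omim)
  rows <- lapply(manifest$trios, function(entry) {
    trio_dir <- file.path(cohort_dir, entry$trio_id)
    ped <- read_pedigree(file.path(trio_dir, "trio.ped"))
    profile <- read_hpo_terms(file.path(trio_dir, "hpo_terms.txt"),
                              patient_id = ped$proband_id)
    clin <- read_gene_list(file.path(trio_dir, "clinician_genes.txt"))
    phase1 <- build_phase1_panel(profile, hpo_map, clin)
    report <- triage_trio(
      file.path(trio_dir, "trio.vcf"), ped, phase1, phase2, acmg,
      cfg = cfg, opt_in_secondary = opt_in_secondary,
      mdt_decision = mdt_decision,
      out_dir = if (is.null(out_dir)) NULL else file.path(out_dir,
                                                          entry$trio_id)
    )
    top <- if (nrow(report$diagnostic_calls)) report$diagnostic_calls[1, ]
           else NULL
    tibble::tibble(
      trio_id = entry$trio_id,
      outcome = report$outcome,
      top_model = if (is.null(top)) NA_character_ else top$model,
      top_gene = if (is.null(top)) NA_character_ else top$gene,
      phases_run = paste(report$phases_run, collapse = ","),
      n_diagnostic = nrow(report$diagnostic_calls),
      n_secondary = nrow(report$secondary_findings),
      n_research = nrow(report$research_candidates),
      report = list(report)
    )
  })
  dplyr::bind_rows(rows)
}
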