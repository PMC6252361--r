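#' Construct a gene panel
#'
#' A named set of gene symbols with per-gene provenance (which HPO term,
#' clinician list or disease-gene database contributed it) and optional
#' per-gene mode of inheritance. Symbols are deduplicated
#' case-insensitively and stored upper case; alias resolution is not
#' attempted.
#'
#' @param name Panel name.
#' @param genes Character vector of gene symbols.
#' @param provenance Named list mapping gene symbol to a character vector
#'   of sources; built automatically (source `"unspecified"`) if omitted.
#' @param moi_by_gene Optional named character vector mapping gene symbol
#'   to `{recessive, dominant, x_linked, unknown}`.
#' @param universal If `TRUE` the panel is the genome-wide sentinel scope:
#'   membership tests always pass, including for variants in no annotated
#'   gene.
#' @return An object of class `gene_panel`.
#' @export
gene_panel <- function(name, genes = character(), provenance = NULL,
                       moi_by_gene = NULL, universal = FALSE) {
  genes <- toupper(genes[!is.na(genes) & genes != ""])
  if (!universal && !length(genes)) {
    stop("empty panel '", name, "': a non-universal panel needs >= 1 gene",
         call. = FALSE)
  }
  if (is.null(provenance)) {
    provenance <- stats::setNames(
      rep(list("unspecified"), length(unique(genes))), unique(genes))
  } else {
    names(provenance) <- toupper(names(provenance))
    provenance <- lapply(split(unlist(provenance, use.names = FALSE),
                               rep(names(provenance), lengths(provenance))),
                         unique)
  }
  genes <- sort(unique(genes))
  if (!universal && !all(genes %in% names(provenance))) {
    stop("every panel gene needs >= 1 provenance entry", call. = FALSE)
  }
  if (!is.null(moi_by_gene)) {
    names(moi_by_gene) <- toupper(names(moi_by_gene))
    moi_by_gene <- moi_by_gene[!duplicated(names(moi_by_gene))]
  }
  structure(
    list(name = name, genes = genes,
         provenance = if (universal) provenance else provenance[genes],
         moi_by_gene = moi_by_gene, universal = isTRUE(universal)),
    class = "gene_panel"
  )
}

#' @export
print.gene_panel <- function(x, ...) {
  if (x$universal) {
    cat(sprintf("Gene panel <%s>: genome-wide scope (universal)\n", x$name))
  } else {
    cat(sprintf("Gene panel <%s>: %d genes\n", x$name, length(x$genes)))
  }
  invisible(x)
}

#' Is a gene inside a panel's scope?
#'
#' Case-insensitive membership; the universal (phase III) panel contains
#' every gene, including the empty symbol (variants in no annotated gene).
#'
#' @param panel A [gene_panel()].
#' @param genes Character vector of gene symbols (may contain `""`/`NA`).
#' @return Logical vector.
#' @export
panel_contains <- function(panel, genes) {
  stopifnot(inherits(panel, "gene_panel"))
  if (panel$universal) return(rep(TRUE, length(genes)))
  !is.na(genes) & toupper(genes) %in% panel$genes
}

#' Build the bespoke phase I panel from HPO terms and clinician gene lists
#'
#' The phase I scope restricts analysis to genes with a high prior
#' probability of involvement in the patient's disorder: the union of the
#' genes mapped from each of the patient's HPO terms (via a supplied
#' term-to-gene map emulating PanelApp/Phenotips/OMIM Gene Map lookups)
#' and any gene list provided by the referring clinical team. Unknown HPO
#' terms contribute nothing (with a message). Provenance records, per
#' gene, every term and list that contributed it. No ontology propagation
#' is performed: a term contributes only its own mapped genes.
#'
#' @param profile List with elements `patient_id` and `hpo_terms`
#'   (character vector of `HP:NNNNNNN` identifiers), e.g. from
#'   [read_hpo_terms()].
#' @param hpo_gene_map Tibble with columns `term`, `gene` and optionally
#'   `moi`; see [read_hpo_map()].
#' @param clinician_genes Character vector of gene symbols (may be empty).
#' @return A [gene_panel()] named `"phase_I"`.
#' @export
build_phase1_panel <- function(profile, hpo_gene_map,
                               clinician_genes = character()) {
  terms <- unique(profile$hpo_terms)
  bad <- terms[!grepl("^HP:\\d{7}$", terms)]
  if (length(bad)) {
    stop("syntactically invalid HPO term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  hits <- hpo_gene_map[hpo_gene_map$term %in% terms, , drop = FALSE]
  unknown <- setdiff(terms, hpo_gene_map$term)
  if (length(unknown)) {
    message("HPO term(s) not in map (ignored): ",
            paste(unknown, collapse = ", "))
  }
  genes <- c(toupper(hits$gene), toupper(clinician_genes))
  if (!length(genes)) {
    stop("empty phase I panel: no HPO term mapped to a gene and no ",
         "clinician genes supplied", call. = FALSE)
  }
  prov <- c(
    stats::setNames(as.list(paste0("HPO:", hits$term)), toupper(hits$gene)),
    stats::setNames(rep(list("clinician_list"), length(clinician_genes)),
                    toupper(clinician_genes))
  )
  moi <- NULL
  if ("moi" %in% names(hpo_gene_map) && nrow(hits)) {
    moi <- stats::setNames(hits$moi, toupper(hits$gene))
  }
  gene_panel("phase_I", genes, provenance = prov, moi_by_gene = moi)
}

#' Build the phase II disease-gene panel
#'
#' Union of a developmental-disorders gene list (DDG2P-like) and an
#' OMIM-morbid-like list, with per-source provenance.
#'
#' @param ddg2p,omim_morbid Character vectors of gene symbols.
#' @return A [gene_panel()] named `"phase_II"`.
#' @export
build_phase2_panel <- function(ddg2p, omim_morbid) {
  ddg2p <- ddg2p[!is.na(ddg2p) & ddg2p != ""]
  omim_morbid <- omim_morbid[!is.na(omim_morbid) & omim_morbid != ""]
  if (!length(ddg2p) && !length(omim_morbid)) {
    stop("empty phase II panel: both gene lists are empty", call. = FALSE)
  }
  prov <- c(
    stats::setNames(rep(list("DDG2P"), length(ddg2p)), toupper(ddg2p)),
    stats::setNames(rep(list("OMIM_morbid"), length(omim_morbid)),
                    toupper(omim_morbid))
  )
  gene_panel("phase_II", c(ddg2p, omim_morbid), provenance = prov)
}

#' Genome-wide (phase III) scope sentinel
#'
#' Phase III opens the analysis to variants in any gene -- and to variants
#' in no annotated gene. Membership tests on this panel always pass.
#'
#' @return A universal [gene_panel()] named `"phase_III"`.
#' @export
phase3_scope <- function() {
  gene_panel("phase_III", universal = TRUE,
             provenance = list("*" = "phase III genome-wide"))
}

read_tsv_cols <- function(path, n_min, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          quote = "", blank.lines.skip = TRUE)
  if (ncol(df) < n_min) {
    stop(what, " file ", path, ": expected >= ", n_min, " tab-separated ",
         "columns, found ", ncol(df), call. = FALSE)
  }
  df
}

#' Read a one-gene-per-line list file
#'
#' @param path Path to a text file, one gene symbol per line.
#' @return Character vector (possibly empty).
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list file not found: ", path,
                               call. = FALSE)
  x <- readLines(path)
  x <- trimws(x)
  x[x != "" & !startsWith(x, "#")]
}

#' Read a patient HPO term list (one HP:NNNNNNN term per line)
#'
#' @param path Path to the term file.
#' @param patient_id Patient identifier attached to the profile.
#' @return List with `patient_id` and `hpo_terms`.
#' @export
read_hpo_terms <- function(path, patient_id = basename(path)) {
  terms <- read_gene_list(path)
  list(patient_id = patient_id, hpo_terms = unique(terms))
}

#' Read an HPO term-to-gene map
#'
#' Two tab-separated columns `term`, `gene`; an optional third column
#' gives the gene's mode of inheritance
#' (`recessive`/`dominant`/`x_linked`/`unknown`).
#'
#' @param path Path to the TSV map.
#' @return Tibble with columns `term`, `gene` and, when present, `moi`.
#' @export
read_hpo_map <- function(path) {
  df <- read_tsv_cols(path, 2L, "HPO map")
  out <- tibble::tibble(term = df[[1]], gene = df[[2]])
  if (ncol(df) >= 3L) out$moi <- df[[3]]
  out
}

#' Read a medically actionable (ACMG-like) gene list with MOI
#'
#' Two tab-separated columns: gene symbol and mode of inheritance
#' (`recessive`/`dominant`/`x_linked`), used by the secondary-findings
#' scan to require an inheritance-model call consistent with the gene.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene`, `moi`.
#' @export
read_acmg_genes <- function(path) {
  df <- read_tsv_cols(path, 2L, "actionable gene")
  tibble::tibble(gene = toupper(df[[1]]), moi = df[[2]])
}
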