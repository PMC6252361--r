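#' Construct a validated trio pedigree
#'
#' The workflow is built around biological trios: proband plus both
#' parents. The three sample identifiers must be distinct and both parents
#' must be present; proband sex is required before the X-linked model can
#' run.
#'
#' @param family_id Family identifier.
#' @param proband_id,mother_id,father_id Sample identifiers matching the
#'   VCF sample columns.
#' @param proband_sex `"male"`, `"female"` or `"unknown"`.
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(family_id, proband_id, mother_id, father_id,
                     proband_sex = c("male", "female", "unknown")) {
  proband_sex <- match.arg(proband_sex)
  ids <- c(proband_id, mother_id, father_id)
  if (any(is.na(ids)) || any(ids == "" | ids == "0")) {
    stop("incomplete trio: proband, mother and father ids are all required",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("pedigree format error: duplicate sample id '",
         ids[duplicated(ids)][1], "'", call. = FALSE)
  }
  structure(
    list(family_id = as.character(family_id),
         proband_id = as.character(proband_id),
         mother_id = as.character(mother_id),
         father_id = as.character(father_id),
         proband_sex = proband_sex),
    class = "pedigree"
  )
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Trio pedigree <%s>: proband %s (%s), mother %s, father %s\n",
              x$family_id, x$proband_id, x$proband_sex, x$mother_id,
              x$father_id))
  invisible(x)
}

#' Read a trio pedigree from a 6-column PED file
#'
#' Standard whitespace-delimited PED: family, sample, father, mother, sex
#' (1 = male, 2 = female, other = unknown), phenotype. Exactly one family
#' of exactly three members is accepted; the proband is the row whose
#' father and mother columns name the other two samples.
#'
#' @param path Path to a PED file.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path, call. = FALSE)
  ped <- utils::read.table(
    path, header = FALSE, colClasses = "character", comment.char = "#",
    col.names = c("family_id", "sample_id", "father_id", "mother_id",
                  "sex", "phenotype")
  )
  if (length(unique(ped$family_id)) != 1L) {
    stop("pedigree format error: expected a single family, found ",
         length(unique(ped$family_id)), call. = FALSE)
  }
  if (anyDuplicated(ped$sample_id)) {
    stop("pedigree format error: duplicate sample id '",
         ped$sample_id[duplicated(ped$sample_id)][1], "'", call. = FALSE)
  }
  has_parents <- ped$father_id != "0" & ped$mother_id != "0"
  if (!any(has_parents)) {
    stop("incomplete trio: no sample lists both parents", call. = FALSE)
  }
  proband_row <- ped[has_parents, , drop = FALSE]
  if (nrow(proband_row) != 1L) {
    stop("pedigree format error: expected exactly one proband, found ",
         nrow(proband_row), call. = FALSE)
  }
  trio_ids <- c(proband_row$sample_id, proband_row$mother_id,
                proband_row$father_id)
  extra <- setdiff(ped$sample_id, trio_ids)
  if (length(extra)) {
    stop("trio-only pedigree: extra sample(s) in family: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!all(c(proband_row$mother_id, proband_row$father_id) %in%
             ped$sample_id)) {
    stop("incomplete trio: parent id(s) not present as samples: ",
         paste(setdiff(c(proband_row$mother_id, proband_row$father_id),
                       ped$sample_id), collapse = ", "), call. = FALSE)
  }
  sex <- switch(proband_row$sex, "1" = "male", "2" = "female", "unknown")
  pedigree(proband_row$family_id, proband_row$sample_id,
           proband_row$mother_id, proband_row$father_id, sex)
}

#' Write a trio pedigree to a 6-column PED file
#'
#' @param ped A [pedigree()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  sex_code <- switch(ped$proband_sex, male = "1", female = "2", "0")
  lines <- c(
    paste(ped$family_id, ped$father_id, "0", "0", "1", "1", sep = "\t"),
    paste(ped$family_id, ped$mother_id, "0", "0", "2", "1", sep = "\t"),
    paste(ped$family_id, ped$proband_id, ped$father_id, ped$mother_id,
          sex_code, "2", sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
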