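# Independent brute-force re-evaluation of the filter predicates: a direct,
# row-by-row translation of the filtering rules, deliberately written
# without reusing any package internals. Used to cross-check filter trails.

oracle_standard_freq <- function(v, af_max = 0.005) {
  vapply(seq_len(nrow(v)), function(i) {
    afs <- c(v$af_1000g[i], v$af_exac[i], v$af_evs[i])
    reported <- afs[!is.na(afs)]
    all(reported <= af_max)
  }, logical(1))
}

oracle_permissive_freq <- function(v, af_max = 0.10,
                                   par = data.frame(chrom = "chrX",
                                                    start = 1, end = 50000)) {
  vapply(seq_len(nrow(v)), function(i) {
    afs <- c(v$af_1000g[i], v$af_exac[i], v$af_evs[i])
    reported <- afs[!is.na(afs)]
    if (!all(reported <= af_max)) return(FALSE)
    hom <- v$exac_hom_count[i]
    if (!is.na(hom) && hom > 0) return(FALSE)
    on_x_nonpar <- v$chrom[i] == "chrX" &&
      !any(par$chrom == v$chrom[i] & v$pos[i] >= par$start &
             v$pos[i] <= par$end)
    if (on_x_nonpar) {
      hemi <- v$exac_hemi_count[i]
      if (!is.na(hemi) && hemi > 0) return(FALSE)
    }
    TRUE
  }, logical(1))
}

oracle_deleterious <- function(v, window = 7) {
  lof <- c("snv_deleterious_missense", "frameshift", "start_lost",
           "stop_gained", "stop_lost")
  vapply(seq_len(nrow(v)), function(i) {
    cq <- v$consequence[i]
    if (cq %in% lof) return(TRUE)
    if (cq == "splice_region" && !is.na(v$splice_distance[i]) &&
          abs(v$splice_distance[i]) <= window) return(TRUE)
    FALSE
  }, logical(1))
}

# Minimal variant-row factory for unit tests that bypass VCF round-trips.
make_variants <- function(n = 1, chrom = "chr1", pos = seq(10000, by = 100,
                                                           length.out = n),
                          ref = "A", alt = "G", gene = "SYG1_01",
                          consequence = "stop_gained",
                          splice_distance = NA_integer_,
                          af_1000g = NA_real_, af_exac = NA_real_,
                          af_evs = NA_real_,
                          exac_hom_count = NA_integer_,
                          exac_hemi_count = NA_integer_,
                          known_pathogenic = TRUE,
                          proband_gt = "het", mother_gt = "hom_ref",
                          father_gt = "hom_ref", symbolic = FALSE) {
  v <- tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    gene = rep_len(gene, n), consequence = rep_len(consequence, n),
    splice_distance = as.integer(rep_len(splice_distance, n)),
    af_1000g = rep_len(af_1000g, n), af_exac = rep_len(af_exac, n),
    af_evs = rep_len(af_evs, n),
    exac_hom_count = as.integer(rep_len(exac_hom_count, n)),
    exac_hemi_count = as.integer(rep_len(exac_hemi_count, n)),
    known_pathogenic = rep_len(known_pathogenic, n),
    proband_gt = rep_len(proband_gt, n), mother_gt = rep_len(mother_gt, n),
    father_gt = rep_len(father_gt, n),
    symbolic = rep_len(symbolic, n), from_multiallelic = FALSE,
    chrom_canonical = TRUE
  )
  v$variant_id <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  afs <- cbind(v$af_1000g, v$af_exac, v$af_evs)
  v$max_af <- apply(afs, 1, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  v
}

male_ped <- function() pedigree("FAM", "P", "M", "F", "male")
female_ped <- function() pedigree("FAM", "P", "M", "F", "female")

# Random annotated variants (no VCF involved) for filter property tests.
random_variants <- function(n, seed) {
  withr::with_seed(seed, {
    af <- function() {
      x <- sample(c(NA, 0, 1, 25, 50, 51, 60, 500, 1000, 1001, 2000, 5000),
                  n, replace = TRUE) / 10000
      x
    }
    make_variants(
      n,
      chrom = sample(c("chr1", "chrX"), n, replace = TRUE),
      pos = sample(60000:900000, n),
      consequence = sample(CONSEQUENCE_CATEGORIES, n, replace = TRUE),
      splice_distance = sample(c(NA, 0:12), n, replace = TRUE),
      af_1000g = af(), af_exac = af(), af_evs = af(),
      exac_hom_count = sample(c(NA, 0L, 0L, 1L, 3L), n, replace = TRUE),
      exac_hemi_count = sample(c(NA, 0L, 0L, 1L), n, replace = TRUE)
    )
  })
}
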