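test_that("PED parsing maps roles and sex, and enforces the trio contract", {
  ped_file <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1\tDAD\t0\t0\t1\t1",
               "F1\tMUM\t0\t0\t2\t1",
               "F1\tKID\tDAD\tMUM\t1\t2"), ped_file)
  ped <- read_pedigree(ped_file)
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$proband_id, "KID")
  expect_equal(ped$mother_id, "MUM")
  expect_equal(ped$father_id, "DAD")
  expect_equal(ped$proband_sex, "male")

  # father id "0": incomplete trio
  writeLines(c("F1\tMUM\t0\t0\t2\t1",
               "F1\tKID\t0\tMUM\t1\t2"), ped_file)
  expect_error(read_pedigree(ped_file), "incomplete trio")

  # four members of one family: error naming the extra sample
  writeLines(c("F1\tDAD\t0\t0\t1\t1",
               "F1\tMUM\t0\t0\t2\t1",
               "F1\tKID\tDAD\tMUM\t2\t2",
               "F1\tUNCLE\t0\t0\t1\t1"), ped_file)
  expect_error(read_pedigree(ped_file), "UNCLE")

  expect_error(pedigree("F1", "A", "A", "B"), "duplicate")
  expect_error(pedigree("F1", "A", "B", "0"), "incomplete trio")
})

test_that("chromosome labels normalize to one dialect, unknown contigs pass through", {
  expect_equal(normalize_chrom("X"), "chrX")
  expect_equal(normalize_chrom("chr7"), "chr7")
  expect_equal(normalize_chrom(c("1", "MT", "chrY")),
               c("chr1", "chrM", "chrY"))
  expect_equal(normalize_chrom("GL000220.1"), "GL000220.1")
  expect_false(is_canonical_chrom("GL000220.1"))
  expect_true(all(is_canonical_chrom(c("chr1", "X", "22"))))
})

test_that("reading a trio VCF enforces samples and maps missing annotations to absent", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=AF_EXAC,Number=1,Type=Float,Description=\"af\">",
    "##INFO=<ID=CSQ_CAT,Number=1,Type=String,Description=\"csq\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP\tM\tF",
    paste0("chr1\t100\t.\tA\tG\t.\tPASS\tAF_EXAC=.;CSQ_CAT=stop_gained;",
           "GENE=G1\tGT\t0/1\t0/0\t0/0"),
    "chr1\t200\t.\tC\tT\t.\tPASS\tCSQ_CAT=synonymous;GENE=G1\tGT\t0/0\t0/1\t0/0"
  ), vcf)
  ped <- pedigree("F1", "P", "M", "F", "male")
  v <- suppressWarnings(read_trio_vcf(vcf, ped, toy_filter_config()))
  expect_equal(nrow(v), 2L)
  expect_true(is.na(v$af_exac[1]))       # "." is absent, never 0
  expect_true(all(is.na(v$af_1000g)))    # key absent from header -> absent
  expect_equal(v$proband_gt, c("het", "hom_ref"))
  expect_equal(v$variant_id[1], "chr1:100:A:G")

  bad_ped <- pedigree("F1", "P", "M", "F2", "male")
  expect_error(suppressWarnings(read_trio_vcf(vcf, bad_ped)),
               "sample not found")
})

test_that("multiallelic decomposition recodes genotypes per alt allele", {
  raw <- tibble::tibble(
    chrom = "chr1", pos = 500L, ref = "A",
    alts = list(c("G", "T")),
    gt_proband = "1/2", gt_mother = "0/1", gt_father = "0/2",
    gene = "G1"
  )
  out <- decompose_multiallelic(raw)
  expect_equal(nrow(out), 2L)
  expect_true(all(out$from_multiallelic))
  expect_false(any(out$symbolic))
  # proband 1/2 is het with respect to each alt; parents carry one each
  expect_equal(out$gt_proband, c("0/1", "0/1"))
  expect_equal(out$gt_mother, c("0/1", "0/0"))
  expect_equal(out$gt_father, c("0/0", "0/1"))

  # identity case: single alt comes back unflagged
  one <- decompose_multiallelic(tibble::tibble(
    chrom = "chr1", pos = 1L, ref = "A", alts = list("G"),
    gt_proband = "0/1", gt_mother = "0/0", gt_father = "0/0"
  ))
  expect_equal(nrow(one), 1L)
  expect_false(one$from_multiallelic)

  # symbolic alt passes through flagged, genotypes untouched
  sym <- decompose_multiallelic(tibble::tibble(
    chrom = "chr1", pos = 2L, ref = "A", alts = list("<DEL>"),
    gt_proband = "0/1", gt_mother = "0/0", gt_father = "0/0"
  ))
  expect_true(sym$symbolic)
})

test_that("genotype recoding matches hand enumeration over all GT pairs with 2 alts", {
  # independent oracle: allele a recoded w.r.t. alt i is 1 iff a == i
  alleles <- c("0", "1", "2")
  combos <- expand.grid(a = alleles, b = alleles, stringsAsFactors = FALSE)
  gts <- paste(combos$a, combos$b, sep = "/")
  for (i in 1:2) {
    # sorted (unphased) convention: ref allele printed first
    expected <- vapply(seq_len(nrow(combos)), function(k) {
      paste(sort(ifelse(c(combos$a[k], combos$b[k]) == as.character(i),
                        "1", "0")),
            collapse = "/")
    }, character(1))
    raw <- tibble::tibble(
      chrom = "chr1", pos = seq_along(gts), ref = "A",
      alts = replicate(length(gts), c("G", "T"), simplify = FALSE),
      gt_proband = gts, gt_mother = "0/0", gt_father = "0/0"
    )
    out <- decompose_multiallelic(raw)
    got <- out$gt_proband[out$allele_index == i]
    expect_equal(got, expected, info = paste("alt allele", i))
  }
})

test_that("decomposition conserves allele evidence and genotype states stay in-model", {
  withr::with_seed(7, {
    n <- 40
    n_alts <- sample(1:3, n, replace = TRUE)
    alts <- lapply(n_alts, function(k) {
      a <- sample(c("G", "T", "C", "<DEL>"), k)
      a
    })
    gt_pool <- c("0/0", "0/1", "1/1", "1/2", "2/2", "./.", "0/2")
    raw <- tibble::tibble(
      chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alts = alts,
      gt_proband = sample(gt_pool, n, TRUE),
      gt_mother = sample(gt_pool, n, TRUE),
      gt_father = sample(gt_pool, n, TRUE)
    )
    out <- decompose_multiallelic(raw)
    expect_equal(sum(!out$symbolic),
                 sum(vapply(alts, function(a) sum(!grepl("^<", a)),
                            integer(1))))
    # every non-symbolic decomposed genotype encodes into the 5-state model
    cfg <- toy_filter_config()
    ok <- out[!out$symbolic, ]
    states <- encode_genotypes(ok$gt_proband, "male", ok$chrom, ok$pos, cfg)
    expect_true(all(states %in% GT_STATES))
  })
})

test_that("write + re-read round-trips every annotation and genotype field", {
  gt <- synthetic_gene_table()
  dir <- withr::local_tempdir()
  design <- trio_design("rt", model = "ar_compound_het", n_background = 120)
  generate_trio(design, dir, seed = 5, causal_gene = gt[2, ],
                cfg = toy_filter_config())
  ped <- read_pedigree(file.path(dir, "trio.ped"))
  cfg <- toy_filter_config()
  v1 <- read_trio_vcf(file.path(dir, "trio.vcf"), ped, cfg)
  out <- withr::local_tempfile(fileext = ".vcf")
  write_trio_vcf(v1, ped, out, cfg = cfg)
  v2 <- read_trio_vcf(out, ped, cfg)
  cols <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
            "splice_distance", "af_1000g", "af_exac", "af_evs",
            "exac_hom_count", "exac_hemi_count", "known_pathogenic",
            "proband_gt", "mother_gt", "father_gt", "variant_id")
  expect_identical(as.data.frame(v1[, cols]), as.data.frame(v2[, cols]))
})

test_that("genotype quality gate drops low-quality records at read time", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##INFO=<ID=CSQ_CAT,Number=1,Type=String,Description=\"csq\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP\tM\tF",
    "chr1\t100\t.\tA\tG\t.\tPASS\tCSQ_CAT=stop_gained\tGT:GQ:DP\t0/1:99:30\t0/0:99:30\t0/0:10:30",
    "chr1\t200\t.\tA\tG\t.\tPASS\tCSQ_CAT=stop_gained\tGT:GQ:DP\t0/1:99:30\t0/0:99:30\t0/0:99:30"
  ), vcf)
  ped <- pedigree("F1", "P", "M", "F", "male")
  v <- suppressWarnings(read_trio_vcf(vcf, ped, toy_filter_config()))
  expect_equal(nrow(v), 1L)  # GQ 10 in father fails the gate
  expect_equal(attr(v, "n_qc_dropped"), 1L)
  expect_equal(v$pos, 200L)
})
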