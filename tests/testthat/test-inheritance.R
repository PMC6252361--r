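cfg <- toy_filter_config()

trio_states <- expand.grid(p = GT_STATES, m = GT_STATES, f = GT_STATES,
                           stringsAsFactors = FALSE)

test_that("single-variant models agree with the exhaustive 125-configuration oracle", {
  # independent truth tables, written straight from the genetic definitions
  oracle_dn <- with(trio_states,
                    p == "het" & m == "hom_ref" & f == "hom_ref")
  oracle_arhom_auto <- with(trio_states,
                            p == "hom_alt" & m == "het" & f == "het")
  oracle_xl_male <- with(trio_states,
                         p == "hemi_alt" & f == "hom_ref" &
                           m %in% c("het", "hom_ref"))
  oracle_arhom_female_x <- with(trio_states,
                                p == "hom_alt" & m == "het" &
                                  f == "hemi_alt")

  for (i in seq_len(nrow(trio_states))) {
    auto_v <- make_variants(1, chrom = "chr1", pos = 1000L,
                            proband_gt = trio_states$p[i],
                            mother_gt = trio_states$m[i],
                            father_gt = trio_states$f[i])
    x_v <- make_variants(1, chrom = "chrX", pos = 200000L, gene = "SYGX_01",
                         proband_gt = trio_states$p[i],
                         mother_gt = trio_states$m[i],
                         father_gt = trio_states$f[i])
    info <- sprintf("(%s, %s, %s)", trio_states$p[i], trio_states$m[i],
                    trio_states$f[i])
    expect_equal(nrow(call_de_novo(auto_v)), as.integer(oracle_dn[i]),
                 info = paste("de novo", info))
    expect_equal(nrow(call_ar_homozygous(auto_v, male_ped(), cfg)),
                 as.integer(oracle_arhom_auto[i]),
                 info = paste("ar hom", info))
    expect_equal(nrow(call_x_linked(x_v, male_ped(), cfg)),
                 as.integer(oracle_xl_male[i]),
                 info = paste("x linked", info))
    expect_equal(nrow(call_ar_homozygous(x_v, female_ped(), cfg)),
                 as.integer(oracle_arhom_female_x[i]),
                 info = paste("female-X ar hom", info))
  }
})

test_that("de novo and AR homozygous calls are mutually exclusive", {
  for (i in seq_len(nrow(trio_states))) {
    v <- make_variants(1, proband_gt = trio_states$p[i],
                       mother_gt = trio_states$m[i],
                       father_gt = trio_states$f[i])
    both <- nrow(call_de_novo(v)) > 0 &&
      nrow(call_ar_homozygous(v, male_ped(), cfg)) > 0
    expect_false(both)
  }
})

test_that("X-linked calls carry origin and the forced de novo on X is flagged", {
  xv <- make_variants(1, chrom = "chrX", pos = 300000L, gene = "SYGX_02",
                      proband_gt = "hemi_alt", mother_gt = "het",
                      father_gt = "hom_ref")
  call <- call_x_linked(xv, male_ped(), cfg)
  expect_equal(call$parental_origin, "maternal")

  xv$mother_gt <- "hom_ref"
  call <- call_x_linked(xv, male_ped(), cfg)
  expect_equal(call$flags, "de_novo_on_X")

  # unknown proband sex: the model cannot run
  unknown <- pedigree("FAM", "P", "M", "F", "unknown")
  expect_equal(nrow(call_x_linked(xv, unknown, cfg)), 0L)

  # female proband, het on X: not hemizygous, no call from this model
  fv <- make_variants(1, chrom = "chrX", pos = 300000L,
                      proband_gt = "het", mother_gt = "het",
                      father_gt = "hom_ref")
  expect_equal(nrow(call_x_linked(fv, female_ped(), cfg)), 0L)

  # PAR variants are autosomal: no X-linked call inside the mask
  pv <- make_variants(1, chrom = "chrX", pos = 10000L,
                      proband_gt = "hemi_alt", mother_gt = "het",
                      father_gt = "hom_ref")
  expect_equal(nrow(call_x_linked(pv, male_ped(), cfg)), 0L)
})

test_that("compound het pairing reports exactly the trans pairs", {
  mk <- function(mother, father, pos) {
    make_variants(1, pos = pos, gene = "SYG1_05", proband_gt = "het",
                  mother_gt = mother, father_gt = father)
  }
  # one maternal + one paternal: one pair
  v <- dplyr::bind_rows(mk("het", "hom_ref", 100L), mk("hom_ref", "het", 200L))
  pairs <- call_compound_het(v, male_ped(), cfg)
  expect_equal(nrow(pairs), 1L)
  expect_equal(sort(c(pairs$parental_origin, pairs$partner_origin)),
               c("maternal", "paternal"))

  # both paternal (cis): nothing
  v <- dplyr::bind_rows(mk("hom_ref", "het", 100L), mk("hom_ref", "het", 200L))
  expect_equal(nrow(call_compound_het(v, male_ped(), cfg)), 0L)

  # three hets {maternal, maternal, paternal}: brute force gives 2 pairs
  v3 <- dplyr::bind_rows(mk("het", "hom_ref", 100L), mk("het", "hom_ref", 200L),
                         mk("hom_ref", "het", 300L))
  origins <- classify_parental_origin(v3$mother_gt, v3$father_gt)
  brute <- 0L
  for (a in 1:2) for (b in (a + 1):3) {
    if (sort(c(origins[a], origins[b]))[1] == "maternal" &&
          sort(c(origins[a], origins[b]))[2] == "paternal") {
      brute <- brute + 1L
    }
  }
  got <- call_compound_het(v3, male_ped(), cfg)
  expect_equal(nrow(got), brute)
  expect_equal(nrow(got), 2L)
})

test_that("compound het pairs are order-invariant and one-per-parent", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(2:6, 1)
      v <- make_variants(
        n, gene = "SYG1_07", pos = sample(50000:60000, n),
        proband_gt = "het",
        mother_gt = sample(c("het", "hom_ref"), n, TRUE),
        father_gt = sample(c("het", "hom_ref"), n, TRUE)
      )
      a <- call_compound_het(v, male_ped(), cfg)
      b <- call_compound_het(v[sample(n), ], male_ped(), cfg)
      key <- function(df) sort(paste(pmin(df$variant_id, df$partner_id),
                                     pmax(df$variant_id, df$partner_id)))
      expect_equal(key(a), key(b))
      if (nrow(a)) {
        expect_true(all(sort(c(a$parental_origin[1], a$partner_origin[1])) ==
                          c("maternal", "paternal")))
      }
    }
  })
})

test_that("hets seen in both parents pair only under the unresolved-phase flag", {
  v <- dplyr::bind_rows(
    make_variants(1, pos = 100L, gene = "SYG1_08", proband_gt = "het",
                  mother_gt = "het", father_gt = "het"),
    make_variants(1, pos = 200L, gene = "SYG1_08", proband_gt = "het",
                  mother_gt = "het", father_gt = "hom_ref")
  )
  expect_equal(nrow(call_compound_het(v, male_ped(), cfg)), 0L)
  relaxed <- toy_filter_config(allow_unresolved_phase = TRUE)
  got <- call_compound_het(v, male_ped(), relaxed)
  expect_equal(nrow(got), 1L)
  expect_equal(got$flags, "phase_unresolved")
})

test_that("single deleterious hets in recessive panel genes are shortlisted", {
  moi <- c(SYG1_09 = "recessive", SYG1_10 = "dominant")
  lone <- make_variants(1, gene = "SYG1_09", proband_gt = "het",
                        mother_gt = "het", father_gt = "hom_ref")
  out <- shortlist_single_hets(lone, moi, male_ped(), cfg)
  expect_equal(nrow(out), 1L)
  expect_match(out$reason, "recessive")

  # two hets in trans are a compound het, not a shortlist entry
  pair <- dplyr::bind_rows(
    make_variants(1, pos = 100L, gene = "SYG1_09", proband_gt = "het",
                  mother_gt = "het", father_gt = "hom_ref"),
    make_variants(1, pos = 200L, gene = "SYG1_09", proband_gt = "het",
                  mother_gt = "hom_ref", father_gt = "het")
  )
  expect_equal(nrow(shortlist_single_hets(pair, moi, male_ped(), cfg)), 0L)

  # dominant-MOI gene: no shortlist
  dom <- make_variants(1, gene = "SYG1_10", proband_gt = "het",
                       mother_gt = "het", father_gt = "hom_ref")
  expect_equal(nrow(shortlist_single_hets(dom, moi, male_ped(), cfg)), 0L)
})

test_that("Mendelian consistency classifies the canonical configurations", {
  mk <- function(p, m, f, chrom = "chr1", pos = 1000L) {
    make_variants(1, chrom = chrom, pos = pos, proband_gt = p,
                  mother_gt = m, father_gt = f)
  }
  expect_equal(mendelian_consistency(mk("hom_alt", "hom_ref", "het"),
                                     male_ped(), cfg), "inconsistent")
  expect_equal(mendelian_consistency(mk("het", "het", "het"),
                                     male_ped(), cfg), "consistent")
  expect_equal(mendelian_consistency(mk("het", "missing", "hom_ref"),
                                     male_ped(), cfg), "untestable")
  # the de novo configuration is labelled separately, not plain inconsistent
  expect_equal(mendelian_consistency(mk("het", "hom_ref", "hom_ref"),
                                     male_ped(), cfg), "de_novo_het")
  # hom_alt proband with hom_ref parents: double de novo is not a call
  expect_equal(mendelian_consistency(mk("hom_alt", "hom_ref", "hom_ref"),
                                     male_ped(), cfg), "inconsistent")
  expect_equal(nrow(call_de_novo(mk("hom_alt", "hom_ref", "hom_ref"))), 0L)
  # male X: proband allele must come from the mother
  expect_equal(mendelian_consistency(
    mk("hemi_alt", "hom_ref", "hom_ref", chrom = "chrX", pos = 200000L),
    male_ped(), cfg), "inconsistent")
  expect_equal(mendelian_consistency(
    mk("hemi_alt", "het", "hom_ref", chrom = "chrX", pos = 200000L),
    male_ped(), cfg), "consistent")
})

test_that("parental origin classification covers all carrier configurations", {
  expect_equal(
    classify_parental_origin(
      c("het", "hom_ref", "het", "hom_ref", "missing"),
      c("hom_ref", "het", "het", "hom_ref", "het")),
    c("maternal", "paternal", "unresolved", "none", "untestable")
  )
  # hemizygous father on X counts as a carrier
  expect_equal(classify_parental_origin("hom_ref", "hemi_alt"), "paternal")
})
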