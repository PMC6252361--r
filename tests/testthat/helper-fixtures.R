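# Shared small-scale fixture cohort (150 background variants per trio) so
# unit tests do not regenerate it per test file. The acceptance tests use
# the full-scale cohort (2000 background variants) independently.

.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$dir)) {
    dir <- file.path(tempdir(), "triotriage-small-fixture")
    manifest <- generate_fixture_cohort(dir, seed = 11, n_background = 150)
    .fixture_cache$dir <- dir
    .fixture_cache$manifest <- manifest
  }
  list(dir = .fixture_cache$dir, manifest = .fixture_cache$manifest)
}

small_fixture_results <- function() {
  if (is.null(.fixture_cache$results)) {
    fx <- small_fixture()
    .fixture_cache$results <- suppressMessages(
      triage_cohort(fx$dir, opt_in_secondary = TRUE)
    )
  }
  .fixture_cache$results
}

trio_paths <- function(dir, trio_id) {
  list(vcf = file.path(dir, trio_id, "trio.vcf"),
       ped = file.path(dir, trio_id, "trio.ped"))
}
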