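# triotriage

Phased prioritisation of candidate disease-causing variants from trio
(proband + both parents) whole-genome sequencing, for rapid rare-disease
diagnosis. The package is aimed at clinical bioinformaticians building or
evaluating trio triage pipelines: it takes an annotated multi-sample VCF, a
pedigree, the patient's HPO terms and a set of gene-list resources, and
returns a ranked, auditable shortlist of candidate variants per analysis
phase — plus a synthetic trio-cohort generator so the whole workflow can be
exercised and regression-tested without access to patient genomes.

## The method

A variant *v* with trio genotypes (proband, mother, father) survives
filtering when

- **rarity**: every *reported* population frequency satisfies
  AF_db(v) ≤ 0.005 for db ∈ {1000G, ExAC, EVS} (conjunctive, inclusive;
  absent = not observed = rare), or — for recessive/X-linked searches
  only — the permissive rule AF_db(v) ≤ 0.10 with zero reported ExAC
  homozygotes (and zero hemizygotes on X outside the PAR);
- **consequence**: v is a deleterious-flagged missense SNV, frameshift,
  start/stop change, or a splice-region variant with |splice distance| ≤ 7 bp.

Survivors are classified under four trio inheritance models:

| model | proband | mother | father |
|---|---|---|---|
| de novo | 0/1 | 0/0 | 0/0 |
| AR homozygous | 1/1 | 0/1 | 0/1 |
| AR compound het | 0/1 + 0/1 same gene | carries one | carries the other (trans) |
| X-linked (male, non-PAR) | 1 (hemi) | 0/1 or 0/0 | 0/0 |

Compound heterozygotes are phased through the trio: a pair is reported only
when one variant is carried solely by each parent; variants seen in both
parents are unphaseable and excluded by default. Lone deleterious
heterozygotes in recessive-MOI phase I panel genes are shortlisted for
manual structural-variant review.

Analysis escalates through three scopes — phase I (bespoke HPO + clinician
gene panel), phase II (DDG2P-like + OMIM-morbid-like panels, with an opt-in
ACMG-style secondary-findings scan), phase III (genome-wide, research-only)
— stopping as soon as a finding fully explains the phenotype. Outcomes are
`provisional_finding` or `no_primary_findings`.

## Worked example

Generate a 24-trio synthetic cohort (10 planted causal variants, 1
secondary-findings plant, 13 background-only trios) and triage it:

```r
library(triotriage)

dir <- tempfile("cohort")
generate_fixture_cohort(dir, seed = 17, n_background = 500)
res <- triage_cohort(dir, opt_in_secondary = TRUE)

table(res$outcome)
#> no_primary_findings provisional_finding
#>                  14                  10

table(res$top_model[res$outcome == "provisional_finding"])
#> ar_compound_het   ar_homozygous         de_novo
#>               3               3               4

res$report[[1]]$diagnostic_calls[1, c("model", "gene", "variant_id",
                                      "parental_origin", "phase", "rank")]
#>     model    gene     variant_id parental_origin phase rank
#> 1 de_novo SYG1_01 chr1:29923:A:G            none     I    1
```

The 10 trios carrying a planted causal variant — and only those — come back
with a provisional finding, each in phase I with the planted inheritance
model ranked first. Trio 11 carries only a homozygous plant in an
actionable gene outside the primary panels; it reports
`no_primary_findings` with exactly one secondary finding (`SYG7_15`),
surfaced during phase II and only because `opt_in_secondary = TRUE`. Every
outcome is deterministic in the seed.

Single trios can be run directly: `read_pedigree()`, `read_trio_vcf()`,
`build_phase1_panel()`, then `triage_trio()`; see `?triage_trio`. A thin
CLI wrapper lives in `inst/exec/triotriage.R`.

## Acceptance script

`scripts/acceptance.R` regenerates the standard fixture cohort from
scratch, runs the full phased pipeline (opt-in secondary findings,
automatic escalation) on all 24 trios, and writes the number of trios with
a provisional primary finding as JSON:

```sh
Rscript scripts/acceptance.R --seed 17 --out results/acceptance.json
```

## Repository layout

- `R/` — variant IO (VCF/PED), filters, inheritance models, panel
  construction, phased pipeline, synthetic cohort generator
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/trio-triage-workflow.Rmd` — the model, parameters and design
  choices in full
- `scripts/acceptance.R` — end-to-end acceptance run
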