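---
title: "Phased trio variant triage: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phased trio variant triage: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotriage)
```

## The diagnostic problem

Critically ill children with a suspected monogenic disorder benefit from a
molecular diagnosis in days, not months. Sequencing the affected child
together with both biological parents (a trio) makes variant inheritance
directly observable, which is what turns a genome's worth of variation into
a tractable shortlist: a de novo allele, a homozygous recessive genotype
with two carrier parents, two heterozygous hits in the same gene arriving
one from each parent, or a hemizygous X allele in a boy are each visible as
a specific trio genotype configuration.

`triotriage` implements the variant-prioritisation half of such a rapid
diagnostic workflow: everything downstream of an annotated multi-sample VCF
and upstream of human review. Read mapping, variant calling and consequence
annotation are consumed, not computed; pathogenicity classification and the
decision that a finding "explains the phenotype" belong to a clinical
review meeting and are represented as inputs (a curated `known_pathogenic`
flag, an `mdt_decision` argument), never computed.

## The filtering model

A candidate variant must satisfy three predicates, each recorded per
variant in a filter trail:

1. **Rarity.** Every *reported* population allele frequency -- 1000
   Genomes, ExAC and EVS are carried as separate annotations -- must be at
   or below `af_standard_max` (default 0.005, i.e. 0.5%, inclusive). The
   test is conjunctive: a variant common in any one database fails, because
   a variant common anywhere is a poor Mendelian candidate. A frequency the
   databases do not report is *absent*, never zero: novel variants must
   survive, so absent values are ignored rather than failed.

2. **Permissive rarity for recessive carriage.** Recessive and X-linked
   alleles can segregate at appreciable carrier frequency while remaining
   plausibly pathogenic, provided nobody healthy carries two copies. The
   complementary rule admits variants with all reported frequencies at or
   below `af_permissive_max` (default 0.10, inclusive) *and* zero reported
   ExAC homozygotes -- and zero hemizygotes for X variants outside the
   pseudoautosomal regions. This path is available only to the recessive
   and X-linked model searches; de novo candidates always use the standard
   threshold (a 10%-frequency "de novo" is a genotyping artefact, not a
   candidate).

3. **Predicted deleteriousness.** The consequence category must be one of
   the protein-breaking classes (deleterious-flagged missense SNV,
   frameshift, start/stop codon changes) or a splice-region variant within
   `splice_window_bp` (default 7) base pairs of an exon boundary. The
   window is measured on the annotator-supplied `splice_distance` field,
   defined here as distance to the nearest exon boundary -- a declared
   convention, since splice annotations vary between annotators. A
   splice-region variant with no reported distance cannot be placed inside
   the window and is conservatively dropped.

## The four inheritance models

Surviving variants are classified against the trio genotypes:

* **De novo** -- proband heterozygous, both parents homozygous reference.
  A homozygous-alt proband with reference parents would require two
  independent mutation events; it is flagged Mendelian-inconsistent, not
  called (overwhelmingly genotyping error).
* **Autosomal recessive homozygous** -- proband homozygous alt, both
  parents heterozygous carriers. A homozygous proband with a non-carrier
  parent is inconsistent, not a call; uniparental disomy is not modelled.
* **Autosomal recessive compound heterozygous** -- two heterozygous
  variants in the same gene, phased through the trio: one carried only by
  the mother, one only by the father (trans). Variants carried by both
  parents cannot be phased from the trio and are excluded from pairs by
  default; `allow_unresolved_phase = TRUE` relaxes this, flagging such
  pairs `phase_unresolved`.
* **X-linked** -- male proband hemizygous alt outside the pseudoautosomal
  regions with a non-carrier father; a carrier mother gives maternal
  origin, a non-carrier mother forces a de novo event on X (called, but
  flagged `de_novo_on_X`). Affected females on X are handled by the
  recessive operations with the X-specific transmitting configuration
  (mother het, father hemizygous alt). This male/female split is a
  declared convention. PAR variants are treated as autosomal throughout;
  the PAR masks are build-configurable and default to GRCh37.

Missing parental genotypes make a variant *untestable* for a model rather
than letting it pass silently -- the trio design is the premise of the
whole workflow. A genotype-quality gate (GQ >= 20 and depth >= 8 in all
three samples, configurable) is applied at read time; upstream tools are
silent on this, but de novo calling without a quality floor is
meaningless. In phase I, a lone deleterious heterozygote in a panel gene
with a recessive mode of inheritance is additionally shortlisted as input
to manual structural-variant review (the second hit may be a deletion or
inversion invisible to small-variant calling); the review itself is out of
scope.

## Phased analysis and reporting

Analysis proceeds in three escalating scopes, so that the most probable
genes are reported first and a fully explanatory phase I finding ends the
analysis:

* **Phase I** -- a bespoke panel per patient: the union of genes mapped
  from the patient's HPO terms (via a supplied term-to-gene TSV emulating
  PanelApp/Phenotips/OMIM lookups; no live queries, for reproducibility)
  and gene lists from the referring clinicians. No ontology propagation is
  performed by default: a term contributes only its own mapped genes,
  because panel curation, not ontology inference, is being emulated.
* **Phase II** -- broad disease-gene panels (a DDG2P-like developmental
  disorders list plus an OMIM-morbid-like list). Escalation into phase II
  happens automatically when phase I produced no reportable call, or on an
  explicit `partial`/`unexplained` decision when it did -- "does this
  fully explain the phenotype" is a clinical judgement the pipeline will
  not fake. The `auto` policy used in unattended runs treats any
  reportable call as fully explanatory.
* **Phase III** -- the genome-wide scope, including variants in no
  annotated gene. Its output is research-only and can never produce a
  provisional finding; panels are *independent* scopes, not nested, and
  only phase III is guaranteed to contain the others.

The **secondary-findings scan** runs at phase II breadth only, and only
with explicit opt-in consent: deleterious, frequency-passing variants in a
medically actionable (ACMG-like) gene list whose model call matches the
gene's mode of inheritance, minus anything already reported as primary.
The permissive frequency rule is applied uniformly in all phases (whether
the original workflow re-applied it beyond phase I is unstated; uniform
application is the declared choice here).

Candidates are ranked deterministically: curated-pathogenic assertions
first, then phase, then model priority (de novo, homozygous, compound het,
X-linked), then ascending maximum reported frequency (absent = rarest),
with genomic coordinate as the final tie-break. The report outcome is
`provisional_finding` exactly when a reportable phase I/II call exists,
otherwise `no_primary_findings`; serialization (JSON + TSV) contains no
timestamps, so identical inputs give byte-identical reports.

## The synthetic cohort generator

No patient genomes accompany this package, so validation rests on a
generator of annotated, Mendelian-consistent trio VCFs with planted causal
variants and machine-readable truth manifests.

The toy genome is four 1-Mb contigs (chr1, chr2, chr7, chrX with a 50-kb
pseudoautosomal segment) carrying 100 synthetic genes; the default
background load is 2,000 variants per trio. These sizes are a deliberate
scale-down -- a real trio yields millions of variants -- chosen so a full
24-trio cohort generates and triages in about a minute on one CPU; the
filters are per-variant and per-gene, so their behaviour does not depend
on genome size.

Every background variant is constructed to fail at least one filter
deterministically, from one of three strata: *common* (all three
frequencies 2-30%, at least one ExAC homozygote, so both frequency paths
fail), *benign* (synonymous/intronic/other consequence, or splice-region
beyond the 7-bp window), and *inert* (deleterious and rare, but genotypes
that fit no model and cannot join a compound-het pair: proband homozygous
reference, or het/het/het which is phase-unresolved). Background genotypes
are always Mendelian-consistent -- parents are drawn first and alleles
transmitted -- so the generator never manufactures spurious de novo
events. Allele frequencies are drawn on a 1e-4 grid, which makes VCF
round-trips exact; frequencies are drawn independently per database within
a stratum (their realistic joint distribution is unknowable from any one
source -- a declared simplification). A few background records are written
multiallelic so decomposition is exercised end-to-end.

The standard fixture cohort mirrors the composition of the clinical cohort
this workflow design is drawn from: 24 trios, of which 10 carry a
curated-pathogenic plant in a phase I panel gene (4 de novo, 3
compound-het pairs -- one pair exercising the permissive 5-10% stratum --
and 3 recessive homozygotes), 1 carries only a homozygous secondary plant
in an actionable gene outside all primary panels, and 13 carry background
only. Note the arithmetic: the 14 trios expected to report "no primary
findings" are the 13 background-only trios plus the secondary-plant trio,
whose finding is by definition not primary.

**What a green test establishes, and what it does not.** The fixture
proves the plumbing: scope, filters, models, phasing, escalation, consent
gating and ranking behave exactly as specified on data whose truth is
known. It does not establish clinical sensitivity: real genomes contain
mosaicism, genotyping error, pseudogenes, segmental duplications,
population structure and annotation noise that the generator deliberately
does not model (nor read-level error, coverage variation or structural
variants). The recovered 10/24 is the planted 10/24.

## Numerical and edge-case choices

* Thresholds are inclusive (`<=`), exactly as the percentages are printed
  in diagnostic practice; 0.5% passes the standard filter, 10% with zero
  homozygotes passes the permissive one.
* Coordinates stay 1-based VCF convention end to end.
* Multiallelic records are decomposed to one record per alt allele; other
  alt alleles are recoded to reference for that record, the unphased
  genotype is reported ref-allele-first, and the provenance is flagged.
  Symbolic alts (`<DEL>` etc.) pass through flagged and are excluded from
  filters.
* Unknown contigs are preserved verbatim and flagged non-canonical rather
  than guessed at.
* Gene identity is by symbol, deduplicated case-insensitively; alias
  resolution is a known limitation.
* Annotation INFO keys are configuration-mapped (`field_map`), not
  hard-coded, since annotators differ.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `af_standard_max` | 0.005 | allele fraction | rare-disease rarity ceiling, inclusive |
| `af_permissive_max` | 0.10 | allele fraction | recessive carrier-frequency ceiling, inclusive |
| `splice_window_bp` | 7 | bp | splice-region deleteriousness window |
| `min_gq`, `min_dp` | 20, 8 | phred, reads | trio genotype-quality gate (declared, not sourced) |
| `allow_unresolved_phase` | FALSE | -- | admit unphaseable compound-het pairs |
| `par_regions` | GRCh37 PARs | coordinates | build-configurable PAR masks |
| `n_background` | 2000 | variants/trio | fixture background load (scale-down) |

## Known limitations

Single-trio families only (no siblings, no quads); no statistical de novo
priors or likelihoods; no structural-variant detection (only the het
shortlist that triggers manual review); no mosaicism or uniparental
disomy; no phenotype-similarity ranking -- panels are binary scopes; no
automated pathogenicity scoring. These are boundaries of the emulated
workflow, not oversights.
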