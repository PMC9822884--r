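---
title: "Trio genome-sequencing triage: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio genome-sequencing triage: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triotriage)
library(dplyr)
```

## The problem

Genome sequencing (GS) of a patient–parent trio yields small variants, copy-number
variants (CNVs), short-tandem-repeat (STR) genotypes, runs of homozygosity (ROH) and
mitochondrial variants in a single experiment. Turning those calls into a diagnostic
outcome for a child with a neurodevelopmental disorder (NDD) requires a chain of
filters: genotype quality control, restriction to interpretable sequence, segregation
by mode of inheritance, gene-panel–aware prioritization, and finally a per-patient
outcome classification that can be compared across diagnostic pathways.
`triotriage` implements that chain as composable, tibble-in/tibble-out functions,
together with a synthetic cohort generator so every stage is testable without access
to patient data.

The package ships, as a worked-example fixture, the conclusive-diagnosis variant
table of a reference cohort of 150 NDD patient–parent trios that was analysed in
parallel by an exome-based standard-of-care (SOC) pathway and a GS pathway
(`ndd150_conclusive()`). All cohort-level numbers the package reports are recomputed
from that table or from simulation; none are hard-coded.

## Small-variant triage

**Quality control** (`genotype_qc()`). Verdicts are deterministic and every failure
carries a machine-readable reason code. Defaults, chosen as community-standard trio
thresholds and all configurable through `triage_config()`:

| gate | default |
|---|---|
| depth, every trio member | ≥ 10 reads |
| child heterozygous allele fraction | 0.25–0.75 |
| child homozygous/hemizygous allele fraction | ≥ 0.90 |
| de novo: parental allele fraction | < 0.05 |
| de novo: parental depth | ≥ 10 reads |

**Scope** (`in_scope()`). Interpretation is limited to exonic positions — including
non-coding exons and UTRs — plus a splice-region window of ±8 bp beyond exon
boundaries; deeper intronic positions are excluded. The window is measured in bp from
the exon edge, so an offset of exactly 8 bp is in scope and 9 bp is not. Widening the
window can only add variants (a property the test suite checks).

**Segregation** (`segregate_trio()`). Modes are assigned purely from genotypes, child
sex and chromosome: de novo (child het, both parents reference), homozygous (child
hom-alt, both parents carriers), hemizygous (male child, X outside the
pseudoautosomal regions; PAR coordinates are treated as autosomal and ship as a data
table, `par_regions()`). Child genotypes that cannot be explained by the parents are
flagged `mendelian_inconsistent`; missing parental genotypes suppress only the modes
that need that parent and flag the record, rather than dropping it.

**Compound heterozygotes** (`find_compound_hets()`). Within a gene, two child-het
variants pair when one paternal and one maternal origin assignment exists, or when
one is de novo and the other inherited. Two variants phased to the same parent never
pair; pairs involving an ambiguous origin (both parents carry) are emitted with
`certain = FALSE`. Deletion + small-variant compound heterozygotes in
autosomal-recessive genes are handled analogously (`find_cnv_snv_compound_het()`),
with the extra rule that a small variant physically inside the deletion and phased to
the deletion's haplotype is never paired — it would sit on the deleted allele.

**Prioritization** (`prioritize_small_variants()`). Tier 1 = NDD gene panel, tier 2 =
other established disease genes, tier 3 = candidate disease genes; genes with no
disease annotation are not reported. Frequency gates are per mode: population AF
≤ 0.001 for de novo/dominant, ≤ 0.01 (and zero population homozygotes, when that
count is supplied) for recessive, hemizygous and compound-het candidates. Within a
tier the order is pathogenicity label, then lower population frequency, then
(chrom, pos, alt) lexicographically for reproducibility. Inherited heterozygous P/LP
variants in dominant genes are reported only behind
`include_inherited_dominant = TRUE` (off by default, matching a workflow that filters
for de novo, homozygous, compound-het and hemizygous variants only).

## CNV triage

`segregate_cnv()` matches parental carriage by ≥ 50% reciprocal overlap of same-type
events — a standard CNV inheritance heuristic; the threshold is configurable.
Duplicate calls from depth-based and paired-end/split-read callers are collapsed at
80% reciprocal overlap, keeping the higher-quality record (`merge_cnv_callers()`).

`categorize_cnv()` applies three rules in strict priority: (1) any overlap with an
NDD-panel gene (intronic-only overlap counts by default; `panel_any_overlap = FALSE`
demands exon overlap); (2) ≥ 1 bp overlap with an exon — coding or non-coding — of a
disease gene; (3) ≥ 1 bp exon overlap of any gene for events strictly longer than
10 kb. The 1 bp/non-coding rule matters in practice: a deletion confined to a 3'UTR
exon of a disease gene is still category 2.

Reported sizes (`cnv_report_size()`) follow clinical-table convention: lengths
(end − start + 1) of at least 100 kb round half-up to 0.1 Mb ("0.6 Mb", "1.3 Mb"),
smaller events to the nearest kb ("5 kb", "36 kb"). This rule reproduces every size
label printed in the bundled diagnosis table exactly, which is how the threshold was
fixed.

## STR, ROH and mitochondrial triage

`classify_str()` compares the larger allele at each of the six NDD repeat loci
(*AFF2*, *ARX*, *CSTB*, *EIF4A3*, *DMPK*, *FMR1*) to locus thresholds. The default
catalog uses literature-standard cutoffs (FMR1 premutation 55 / full mutation 200;
AFF2 200; DMPK 50; CSTB 30; ARX 20; EIF4A3 14) and is fully overridable via a TSV —
these defaults stand in for laboratory-specific threshold tables. Any allele at or
above the premutation (or, failing that, pathogenic) threshold raises a confirmation
flag, mirroring the practice of manually curating and PCR-confirming putative
expansions. Whether a premutation-range allele may *support a diagnosis* is a
reporting-layer decision (`premutation_reportable`, default `TRUE`): the reference
cohort's 94-unit FMR1 allele was diagnostic, but laboratories differ here, so the
classification layer never hard-codes it. Loci outside the configured catalog pass
through `unevaluated` rather than erroring, so a broader caller catalog (e.g. 39
disease loci) can be consumed while classification stays restricted to the six.

`detect_roh()` is the classic SNP-count sliding-window scan: 50-SNP windows, at most
3 heterozygous and 5 missing calls per window, a SNP supports a run when ≥ 5% of the
windows covering it are homozygous, and segments must reach 50 SNPs and 300 kb. The
window size, hit proportion and missing allowance are the scan's usual defaults;
the het allowance and the two segment minima are the parameters a typical GS workflow
overrides, and all are configurable (`roh_params()`). ROH output is annotative only:
homozygous candidates inside a segment are tagged as possibly identical by descent
(`annotate_roh()`), but an ROH never constitutes a finding by itself.

`match_mito()` intersects variant calls on the mitochondrial contig with a
confirmed-pathogenic catalog by exact (position, ref, alt) match, carrying the child
allele fraction through as a heteroplasmy proxy. The bundled catalog
(`synthetic_mito_catalog()`) is a deliberately small synthetic snapshot of well-known
confirmed mutations; real analyses should supply a current catalog TSV, and results
depend entirely on the catalog supplied.

## Outcome classification and concordance

`classify_patient()` maps candidates to one of three outcome classes — the
definitions used by diagnostic laboratories:

* **conclusive** — a P/LP variant in an established disease gene compatible with the
  phenotype, with biallelic support (homozygous or compound het, including CNV+SNV
  pairs) required in recessive genes;
* **possible** — a VUS in a disease gene compatible with the phenotype, or a P/LP
  variant in a candidate disease gene;
* **none** — otherwise. A monoallelic P/LP hit in a recessive gene yields rationale
  `monoallelic_recessive` and does not diagnose.

Phenotype compatibility is expert judgment; the package takes it as data (a
per-(patient, gene) flag), never computes it. Pathogenicity labels are likewise
inputs — classification of variants is out of scope by design.

`compare_pathways()` cross-tabulates two pathways' outcomes into a 3×3 concordance
matrix and lists every discordant patient with both outcomes and supporting variant
types; `tidy()`, `glance()` and `autoplot()` give the long form, the one-row summary
(including an unpaired Fisher exact test of the two conclusive yields) and a tile
plot. `tally_diagnoses()` counts each diagnosed patient once, by the variant type of
its *primary* supporting variant: ties on tier, label and frequency resolve by input
row order, so a deliberately ordered support table (such as the bundled published
variant list, where a dual-diagnosis patient's frameshift duplication precedes the
missense SNV) keeps its published precedence.

The two printed yield-comparison p-values of the reference study are built on 2×2
tables whose exact construction is not recoverable from the published marginals; the
package therefore reports the transparent unpaired construction
(43/150 vs 45/150 → p ≈ 0.90) under an explicit name rather than matching a printed
value it cannot derive.

## The synthetic cohort generator

`simulate_cohort()` generates the statistical structure the analysis assumes, not
sequence reads:

* **Pedigrees** — `n_trios` trios (default 150) with a male-proband fraction of
  101/150, the reference cohort's demography.
* **Background variation** — per trio, 120 small-variant sites drawn in and around a
  deterministic synthetic gene panel; parental genotypes are Hardy–Weinberg draws
  from each site's allele frequency and child genotypes are Mendelian transmissions.
  Depth is negative-binomial with mean 50 (the study's genome-wide coverage target),
  heterozygous allele fractions are Beta-distributed around 0.5, and allele-depth
  integers are drawn binomially so written VCFs round-trip exactly. Optional noise:
  a genotype-error rate (random child-genotype replacement, the source of Mendelian
  errors) and a parental-dropout rate. Both default to **zero**: the generator's
  defaults are the conditions under which planted-diagnosis recovery must be exact.
* **Planted causal variants** — the conclusive spectrum defaults to the reference
  cohort's: 45 conclusive diagnoses (26 SNVs, 13 indels, 5 CNVs, 1 FMR1 expansion of
  94 units), 35 possible, 70 undiagnosed; small-variant modes 35 de novo /
  1 homozygous / 3 hemizygous. Counts are fixed from the configured proportions by
  largest-remainder apportionment, so a given configuration always plants exactly
  the same spectrum. Two conclusive CNVs are planted as GS-only archetypes — a
  ~5 kb two-exon deletion (below the SOC detectability floor) and a ~36 kb deletion
  confined to a non-coding 3'UTR exon — as are four possible-outcome small CNVs.
  Planted variants receive QC-clean metrics by construction: the truth-table
  contract is that every plant passes the triage stage appropriate to its type.
* **Two pathway views** — the SOC view (`soc_view()`) is the same cohort minus CNVs
  shorter than a configurable 10 kb floor and minus CNVs whose exon overlap is
  exclusively non-coding. This emulates *why* exome-based CNV calling misses such
  events (sensitivity limits and absent capture targets) without modelling exome
  capture itself, and is what makes concordance analysis testable end to end.
* **Determinism** — one seed drives a single random generator; the same
  configuration reproduces byte-identical cohort files.

What the generator does **not** emulate: linkage disequilibrium and population
structure, realistic allele-frequency spectra, read-level evidence (so no
breakpoint uncertainty or mosaicism), X-chromosome background variation (background
sites are autosomal; X is exercised by planted hemizygous variants), and sequence
context. Passing the recovery tests therefore demonstrates that the *filtering
logic* is correct under clean Mendelian data with known truth — not that the
pipeline is robust to caller artefacts in real data.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; BED input is converted on read.
  CNV length is end − start + 1; ">10 kb" is strict.
* Both ISCN-like copy-number dialects (`...x1` and `...3x`) are accepted; a repeat
  region whose length is not a motif multiple warns but parses (reference repeat
  tracts are often interrupted).
* Fisher's exact test is delegated to `stats::fisher.test` (two-sided by the
  point-probability rule); the test suite holds it to a full hypergeometric
  enumeration oracle. An all-zero table returns p = 1 by convention.
* Prioritization ties break lexicographically; tally ties break by input order;
  caller merging keeps the higher-quality record. All tie-breaks are deterministic.
* Missing population frequencies are treated as 0 (absent from databases = rare);
  missing parental genotypes flag rather than drop records.
* Problem sizes in the test suite: the end-to-end acceptance check runs the full
  150-trio study configuration (about 20 s); unit and property tests use 12–100
  trios, ≤ 500-SNP ROH sequences, ≤ 6-variant compound-het gene sets and 2×2 tables
  with margins ≤ 20, sizes at which the brute-force oracles are exact and fast.

## Known limitations

* Pathogenicity labels, phenotype match and gene-panel membership are inputs; the
  package neither classifies variants nor matches phenotypes.
* Balanced structural variants, mosaic CNVs and breakpoint refinement are out of
  scope; SV input is restricted to DEL/DUP with resolvable ends (others are counted
  and skipped).
* The SOC view is a detectability rule, not an exome simulator; conclusions about
  pathway concordance on synthetic data inherit that simplification.
* ROH detection assumes sorted biallelic genotypes per chromosome and reports
  segments only; it does not estimate inbreeding coefficients.
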