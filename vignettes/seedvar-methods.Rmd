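---
title: "Annotating and analysing variants in microRNA seed regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and analysing variants in microRNA seed regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedvar)
library(dplyr)
```

## The problem

MicroRNAs repress their target mRNAs through base pairing that is dominated
by the *seed region*: nucleotides 2–7 (the minimal 6mer match) or 2–8 (the
extended 7mer match) counted from the 5' end of the mature miRNA. Position 1
is not part of the seed. A polymorphism inside a seed can therefore weaken,
abolish, or — more strikingly — *redirect* target recognition: if the mutant
seed happens to be identical to the seed of a different annotated miRNA, the
variant miRNA inherits that miRNA's target repertoire. The textbook case is
the G>A substitution at position +13 of the miR-96 hairpin (mature position
5), which converts the miR-96 seed into the seed of miR-514 and is associated
with progressive hearing loss.

seedvar is a local, file-based toolkit for this class of analysis. It takes
a miRBase-style GFF3 annotation (hairpins with nested matures), hairpin
sequences in FASTA, variants in VCF, genomic features in BED, host-gene
models in GFF3 and phenotype tables in TSV, and produces tidy tibbles at
every step so analyses compose with the pipe.

## Coordinate model

All internal coordinates are 1-based inclusive — the native convention of
GFF3 and VCF, the two mutation-bearing formats; BED's 0-based half-open
intervals are converted once at the reading boundary (`start + 1`, `end`)
and back on writing. Hairpin sequences are stored 5'→3' in *transcript*
orientation (as in miRBase FASTA) and in the RNA alphabet, so sequence
operations never consult the strand; the strand enters only in the
coordinate arithmetic. For a mature spanning genomic `[s, e]`:

* plus strand: mature position = `g − s + 1`
* minus strand: mature position = `e − g + 1`

so position 1 is always the 5' end of the mature. These maps are exact
inverses, which the test suite asserts base-by-base on generated fixtures,
along with a strand-symmetry property: reverse-complementing the whole
fixture genome and flipping every strand leaves every mature sequence, seed
sequence and annotation invariant.

VCF alleles are kept as given (DNA, + strand) for provenance; annotation
adds transcript-oriented RNA alleles (`ref_rna`, `alt_rna`), complemented on
the minus strand and clipped to the annotated mature, which is what seed
arithmetic consumes.

## Region classification

A variant is classified by the set of *reference* bases it affects:

* SNV — the substituted base;
* MNP — all substituted bases;
* deletion — the deleted bases (the shared VCF anchor base is excluded);
* insertion — the two flanking reference bases, so an insertion strictly
  between two seed positions counts as a seed variant.

For every hairpin the variant touches, each overlapped mature yields one
annotation row: `seed` if any affected base maps to mature positions 2–8,
otherwise `mature_nonseed`; a hairpin hit outside all matures yields one
`precursor` row. Because the 6mer and 7mer definitions are both current in
the field, every row carries both memberships (`seed6_member`, positions
2–7; `seed7_member`, positions 2–8) rather than committing to one; `region
= "seed"` is keyed to the wider 2–8 definition and the 2–7 flag is reported
alongside. A variant inside two overlapping matures is reported once per
mature, since seed membership is mature-specific.

Substitutions are labelled transition (purine ↔ purine, A/G, or pyrimidine ↔
pyrimidine, C/U) or transversion (purine ↔ pyrimidine). The class is
invariant under complementation, so transcript-oriented and genomic alleles
give the same answer; a property test asserts this.

When hairpin sequences are available, each variant's REF is verified against
them. Public variant sets and miRNA annotation builds can disagree, so a
mismatch flags the row (`ref_mismatch = TRUE`) instead of aborting or
dropping it.

## Double-nucleotide polymorphisms

Substitutions at two consecutive positions (DNPs) occur at roughly 1% of the
rate of SNPs and are represented inconsistently in public data: sometimes as
one two-base record, sometimes as two adjacent single-base records.
`merge_dnps()` therefore groups SNVs at genomically adjacent positions
within the same hairpin into maximal runs: runs of length 2 are labelled
`dnp`, longer runs `mnp_run`. The per-SNV member rows are retained and one
derived merged record per run is appended, so the catalog supports both
counting granularities. VCF-native two-base MNP records are accepted as-is
and end up with the same labels downstream. Grouping is idempotent and
independent of input order (tested), and at multiallelic positions the
merged record takes the first ALT per position.

## Seed-switch screen

`find_seed_switches()` re-implements the seed-identity screen as exact
string matching: two seed indexes are built over all annotated matures (k =
6 and k = 7), each variant's mutant mature sequence is computed, and its
mutant seed is looked up. A hit is emitted when the mutant seed equals the
wild-type seed of a *different* mature; self-matches are suppressed, and
because many miRNAs share seeds (seed families), a hit may name several
matures — all are reported. Membership is k-specific: a variant at mature
position 8 leaves the 6mer seed unchanged and can only produce 7mer
switches. Exact equality means recall and precision on planted fixtures are
1.0 with no tolerance involved; a prefix property (a 7mer match implies the
corresponding 6mer match unless the variant sits at position 8) is asserted
in the tests.

`mir96_like_fixture()` packages the canonical worked example: the published
mature sequences of miR-96-5p (`UUUGGCACUAGCACAUUUUUGCU`) and miR-514a-3p
(`AUUGACACUUCUGUGAGUAGA`) embedded in synthetic hairpin flanks and a
synthetic genome (hence the `syn-` names), plus the +13 G>A variant. Running
the screen on it yields exactly one matched miRNA at both k.

## Overlap with QTL, fragile sites and host genes

`intersect_features()` intersects *hairpin spans* (seeds are only 6–7 nt;
overlap statements in this field are made at the miRNA-gene level) with
feature intervals on closed 1-based coordinates: one shared base suffices,
and strict containment is available via `contained = TRUE`. QTL and fragile
sites are treated as unstranded. Host-gene context (`host_gene_context()`)
reports orientation (sense when strands agree) and classifies the hairpin
against the gene's *exon union* — merged exon intervals, so transcript
isoforms are not double-counted: `exonic` when fully covered, `intronic`
when sharing no base with any exon, `exon_and_intron` otherwise; exactly one
of the three holds per overlapping gene. Internally the intersections use
GenomicRanges/IRanges; the tests compare every call against quadratic
double-loop and per-base membership oracles.

## The genotype–phenotype association model

For a seed variant genotyped across a panel of inbred strains, each trait is
fitted by ordinary least squares under the fixed-effects nested model

$$y_{ijkl} = \mu + G_i + L_{j(i)} + S_k + e_{ijkl}$$

with $G_i$ the genotype (two levels, e.g. CC vs TT), $L_{j(i)}$ the strain
nested within genotype (strains are inbred, so genotype is constant within
strain), $S_k$ the sex, and $e_{ijkl}$ random error. The design matrix uses
sum-to-zero coding for the nested strain and sex terms, which makes the
genotype coefficient equal the *difference of genotype least-squares means*
— the coding-invariant quantity reported as `effect` (second sorted genotype
level minus first). Under a balanced design it reduces to the raw difference
of genotype means (asserted to 1e-8); in general it matches an independent
`lm()` + least-squares-means route (`emmeans`), which the tests use as a
cross-check of this implementation.

Two F-test denominators are offered because the classical literature is
split on what the experimental unit is:

* `error = "residual"` (default) — the residual mean square, the default of
  general linear model software; appropriate when individual measurements
  are exchangeable given strain.
* `error = "strain"` — the strain-within-genotype mean square with
  $\sum_i (m_i - 1)$ degrees of freedom, the classical choice when strains
  are the experimental units; with fewer than two strains per genotype it is
  unavailable and the fit falls back with a note.

Both individual-animal measurements and strain means are accepted as input
rows. Degenerate inputs follow conventions rather than erroring: a
zero-variance trait returns effect 0 and p = 1 (avoiding 0/0 F statistics);
a single observed genotype yields a "not estimable" result; single-sex
traits drop $S_k$ with a note.

`scan_traits()` fits every trait and flags `p < alpha` (default 0.01) on the
*raw* p-value — deliberately unadjusted, because a multi-trait screen of
highly correlated phenotype measurements marks *potential groups of affected
traits*, not causal claims; a Benjamini–Hochberg column is available with
`bh = TRUE` for FDR control. `genotype_group_summary()` and
`plot_genotype_means()` provide the per-genotype, per-sex cell summaries
behind a lean-vs-fat strain comparison figure.

## The synthetic fixture generator

`generate_fixture()` builds, deterministically from one seed, a complete toy
study: a genome of i.i.d. uniform bases (a few tens of kb per chromosome),
miRNA hairpins of 80–110 nt on both strands with one or two nested matures
of 20–23 nt, planted SNVs of every region class, planted adjacent-SNV runs
of length 2 and 3, planted seed-switch pairs, QTL/fragile-site intervals,
host genes with controlled exonic context, and a strain-structured phenotype
table — along with a machine-readable ground-truth file that refers only to
entities actually emitted.

Choices that matter for interpreting test results:

* **Seed-switch planting** copies a donor mature's seed into an acceptor
  mature up to one substitution at a position drawn from 2–7 (so both the
  6mer and 7mer switch are planted) and emits that substitution as the
  variant. Random 6mers collide (4^6 = 4096 keys), so an ordinary planted
  seed SNV can *accidentally* create a switch; the generator detects these
  post hoc with its own string logic and records them in the ground truth
  rather than forbidding them — the truth file stays truthful and exact
  recall/precision comparisons remain meaningful.
* **Adjacency control.** Independently planted SNVs are kept at least two
  bases apart so no unplanned DNP runs arise; planted runs live in the
  precursor region so DNP and seed-switch plantings cannot interact.
* **Phenotypes** follow the panel design of a standard inbred-strain
  resource: by default 7 strains per genotype (14 strains), both sexes, 5
  observations per (strain, sex) cell, residual SD 1, a fixed sex effect of
  0.5, and a planted genotype effect of 2 trait units for effect traits.
  Strain-level heterogeneity beyond the genotype effect is deliberately
  absent, so the residual-error genotype test is *exactly* calibrated under
  the null — the type-I simulation checks the machinery, not robustness.
  Real strain panels do show strain variance; with such data the
  residual-denominator p-values are anti-conservative and the
  `error = "strain"` denominator is the defensible choice. This is the main
  respect in which passing tests do not certify behaviour on real data.
* What the fixtures do **not** emulate: hairpin secondary structure and
  thermodynamics, realistic chromosome lengths and variant density, linkage
  between variants, population allele frequencies, and measurement-level
  quirks of real phenotype databases (unbalanced strain coverage, correlated
  traits, single-sex studies) beyond the single-sex code path.

## Problem sizes and numerical choices

The shipped checks run the annotator against a per-base brute-force oracle
on a 200-miRNA / 2000-variant fixture (50% minus strand), the seed-switch
screen on 50 planted pairs among 500 miRNAs, interval overlap on 500 × 200
random intervals against a quadratic double loop, the association model on
200 effect-recovery simulations and 5000 simulated null traits (a
reduced-scale stand-in for a database-wide scan of thousands of traits), and
full generate→analyse→ground-truth identity across 20 seeds. All
equality-style comparisons are exact (string and integer identity); the only
tolerances are 1e-8 on the balanced-design identity, a 2-standard-error
band on simulation bias, and the exact binomial 95% band on the type-I
count. Ties in overlap summaries are listed lexicographically; all output
orderings are deterministic (chromosome, position, name) so equality
comparisons are well-defined.

## Known limitations

* Mature names are assumed unique across the annotation; miRBase duplicates
  (identical matures from paralogous hairpins) would be collapsed by name in
  the seed index — seed-family collapsing by sequence already covers the
  common case.
* The seed-switch screen applies length-preserving substitutions only
  (SNV/MNP/DNP); indel-induced seed changes are annotated by region but not
  screened for switches.
* The association model is fixed-effects only; no REML/mixed-model path is
  provided, by design.
* Functional consequences (target gain/loss scoring, free energy, population
  frequency) are out of scope.
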