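# seedvar

Annotation and analysis of genetic variants in microRNA seed regions.

MicroRNAs repress their targets through base pairing dominated by the
**seed region** — nucleotides 2–7 (6mer) or 2–8 (7mer) from the 5' end of
the mature miRNA; position 1 is excluded. A polymorphism in the seed can
weaken or abolish targeting, or *redirect* it entirely: when the mutant seed
becomes identical to the seed of a different annotated miRNA (a **seed
switch**), the variant miRNA inherits that miRNA's target repertoire, as in
the classic miR-96 +13G>A → miR-514 case associated with hearing loss.

seedvar is a local, file-based toolkit for researchers cataloguing and
prioritising such variants. From standard inputs — miRBase-style GFF3
(hairpins with nested matures), hairpin FASTA, VCF, BED features, host-gene
GFF3, and a strain phenotype table — it:

* maps variants through the genome → hairpin → mature coordinate frames on
  both strands and classifies each as **seed** / **mature_nonseed** /
  **precursor** (6mer and 7mer seed membership reported separately);
* labels substitutions as **transitions** (A↔G, C↔U) or **transversions**
  and merges adjacent SNVs into **double-nucleotide polymorphisms** (DNPs),
  keeping both per-SNV and per-run granularity;
* screens seed variants for **seed switches** by exact seed-string matching
  at k = 6 and k = 7 against an index of all annotated matures;
* intersects polymorphic miRNA genes with **QTL**, **fragile sites** and
  **host genes** (sense/antisense; exonic/intronic/exon-and-intron against
  the exon union);
* scans multi-trait inbred-strain phenotype tables with the fixed-effects
  nested linear model
  *y<sub>ijkl</sub> = μ + G<sub>i</sub> + L<sub>j(i)</sub> + S<sub>k</sub> +
  e<sub>ijkl</sub>* (genotype, strain-within-genotype, sex), reporting the
  genotype effect as the coding-invariant difference of least-squares means
  with its SE and F-test p-value;
* generates **deterministic synthetic fixtures** with machine-readable
  ground truth (planted variants of every class, DNP runs, seed-switch
  pairs, feature overlaps, phenotype effects), so the whole pipeline is
  testable without any downloads.

Everything is tibble-in / tibble-out and composes with the pipe; fitted
models have `tidy()`/`glance()` methods and result tables have ggplot2
helpers (`autoplot()`, `plot_genotype_means()`).

## Worked example

The packaged `mir96_like_fixture()` reproduces the canonical seed-switch
relationship with the published mature sequences of miR-96-5p and
miR-514a-3p embedded in synthetic flanks (hence the `syn-` names):

```r
library(seedvar)
library(dplyr)

fx <- mir96_like_fixture(tempdir())
mirna    <- read_mirna_gff(fx$paths$gff, fasta = fx$paths$fasta)
variants <- read_vcf(fx$paths$vcf)

ann <- annotate_variants(variants, mirna)
ann %>% select(id, pos, ref, alt, mature, region, mature_position, substitution)
#> # A tibble: 1 × 8
#>   id                 pos ref   alt   mature             region mature_position substitution
#>   <chr>            <int> <chr> <chr> <chr>              <chr>            <int> <chr>
#> 1 mir96_plus13_G_A   113 G     A     syn-miR-96-like-5p seed                 5 transition
```

The G>A substitution at hairpin position +13 sits at mature position 5,
inside the seed. Screening it against the seed index of all annotated
matures finds exactly one switch partner, at both seed definitions:

```r
find_seed_switches(ann, mirna) %>%
  select(variant, k, wildtype_seed, mutant_seed, matched_mature)
#> # A tibble: 2 × 5
#>   variant              k wildtype_seed mutant_seed matched_mature
#>   <chr>            <int> <chr>         <chr>       <chr>
#> 1 mir96_plus13_G_A     6 UUGGCA        UUGACA      syn-miR-514-like-3p
#> 2 mir96_plus13_G_A     7 UUGGCAC       UUGACAC     syn-miR-514-like-3p
```

The mutant 7mer seed `UUGACAC` is exactly the miR-514-like seed: the variant
miRNA would be routed to a different target repertoire.

For the association side, simulate a 14-strain inbred panel (7 strains per
genotype, both sexes, 5 observations per cell) with one trait carrying a
planted genotype effect of 2 trait units and scan all traits:

```r
sim  <- simulate_phenotypes(n_null_traits = 3, n_effect_traits = 1,
                            effect_size = 2, seed = 7)
scan_traits(sim$phenotypes, alpha = 0.01)
#> # A tibble: 4 × 8
#>   trait    group                    n_used  effect    se  p_value note  significant
#>   <chr>    <chr>                     <int>   <dbl> <dbl>    <dbl> <chr> <lgl>
#> 1 eff_001  body composition            140  1.82   0.166 4.47e-20 <NA>  TRUE
#> 2 null_001 blood-clinical chemistry    140 -0.199  0.158 2.10e- 1 <NA>  FALSE
#> 3 null_002 blood-hematology            140 -0.0422 0.173 8.08e- 1 <NA>  FALSE
#> 4 null_003 immune system               140  0.0807 0.176 6.47e- 1 <NA>  FALSE

fit_nested_model(sim$phenotypes %>% filter(trait == "eff_001"))
#> Nested fixed-effects genotype model
#>   genotype effect (TT - CC): 1.825 (SE 0.166)
#>   F(1, 125) = 120.8, p = 4.47e-20  [residual error]
#>   n = 140
```

The planted effect (2.0) is recovered as 1.83 ± 0.17; the three null traits
stay non-significant at the α = 0.01 screen. `error = "strain"` switches the
F-test denominator to the strain-within-genotype mean square when strains,
not animals, are the experimental units.

A thin command-line wrapper over the same functions is installed at
`inst/cli/seedvar.R` (subcommands `annotate`, `seed-switch`, `overlap`,
`host-context`, `assoc`, `simulate`).

## Scope

seedvar does not download from miRBase/Ensembl/RGD, render genome views,
predict targets or secondary structure, or fit mixed models; associations
from the trait scan are screening output, not causal claims.
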