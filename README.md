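# scmethkin

Downstream analysis of single-cell bisulfite sequencing (scBS-seq) for
studying how the male germline re-acquires DNA methylation. After
genome-wide erasure in primordial germ cells, prospermatogonia rebuild
methylation over months; because cells in one testis progress
asynchronously, sorting cells by their global CpG methylation level
yields a pseudo-developmental ordering from which regional acquisition
kinetics can be read off. `scmethkin` implements that analysis for
anyone working with per-cell cytosine call tables (Bismark-style
cytosine reports): germ-cell biologists profiling methylation
establishment, and methods people who want a tested, synthetic-data-
validated reference pipeline.

## What it computes

- **Per-cell QC** — bisulfite conversion rate from an unmethylated
  lambda spike-in, CpG dyad coverage rate, and somatic-cell
  contamination flagged by ~50% methylation at maternally methylated
  imprinted DMRs (unmethylated in male germ cells). Cells are excluded
  when coverage < 1% or when imprint methylation marks them somatic.
- **Methylation groups** — per-cell global CpG level (unweighted mean
  of per-dyad rates, strands merged) binned into ordered groups
  G1…Gk; marmoset, cynomolgus and human binning presets ship built in.
- **Kinetic score and classes** — the genome is tiled (500 kbp
  default), group-mean methylation is computed per tile, and each tile
  gets the difference-of-differences score

  S = (m(G3) − m(G1)) − (m(G7) − m(G5))

  (early-phase gain minus late-phase gain; scoring pairs are presets
  per species). Ascending tertiles of S label tiles slow /
  intermediate / fast. Annotation enrichment per class is tested by
  chi-squared on bp-overlap contingencies. The same score applies to
  gene bodies, joined with promoter ATAC accessibility.
- **Context profiles** — mean methylation per annotation category and
  group; genome-wide means recomputed after masking active regions
  (promoters, CpG islands, ATAC peaks ± 2 kb around their midpoints);
  expression tertiles compared by two-sided Wilcoxon tests with
  Benjamini–Hochberg adjustment.
- **Non-CpG methylation** — methylated-call fractions at CG and CH
  dinucleotides per group, with the trinucleotide breakdown of
  methylated CHN (CAC/CAG-dominated) and CGN calls.
- **Synthetic cohorts** — `build_genome()` / `simulate_cells()` /
  `emit_fixture()` generate a toy annotated genome and a cohort of
  single-cell methylomes plus expression, with planted tile classes,
  active-region hypomethylation, imprint-based somatic cells, a lambda
  spike-in with imperfect conversion, and CH motif preferences — all
  with ground-truth labels, so every stage above is validated by
  recovery tests.

## Worked example

```r
library(scmethkin)
library(dplyr)

genome <- build_genome(genome_config(chrom_sizes = c(chr1 = 1e6),
                                     n_genes = 10, seed = 3))
cohort <- simulate_cells(genome, kinetic_model(seed = 4), n_cells = 40,
                         coverage_fraction = 0.2,
                         ch_coverage_fraction = 0.02)

dmrs <- filter(genome$annotations, category == "imprint_dmr")
qc <- qc_cells(cohort$calls, cohort$sheet, dmrs,
               count_cpg_dyads(genome), cpg = cohort$cpg)
filtered <- apply_exclusions(cohort$sheet, qc)
sum(filtered$included)
#> [1] 40

keep <- filtered$cell_id[filtered$included]
cpg <- filter(cohort$cpg, cell_id %in% keep)
assignment <- assign_groups(cell_methylation_levels(cpg),
                            group_scheme("marmoset"))
group_counts(assignment)
#> # A tibble: 7 × 2
#>   group     n
#>   <fct> <int>
#> 1 G1        4
#> 2 G2        0
#> 3 G3        5
#> 4 G4        7
#> 5 G5        9
#> 6 G6        5
#> 7 G7       10

tm <- tile_group_means(cpg, assignment, genome$chrom_sizes,
                       tile_size = 1e5, min_sites = 50)
tk <- classify_kinetics(kinetic_score(tm))
glance(tk)
#> # A tibble: 1 × 6
#>   n_tiles n_scored n_fast n_intermediate n_slow median_score
#>     <int>    <int>  <int>          <int>  <int>        <dbl>
#> 1      10       10      3              3      4      -0.0116

annotation_enrichment(tk, filter(genome$annotations, category == "gene")) |>
  select(class, ratio, p_value)
#> # A tibble: 3 × 3
#>   class        ratio p_value
#>   <chr>        <dbl>   <dbl>
#> 1 fast         2.00        0
#> 2 intermediate 0.687       0
#> 3 slow         0.483       0

mp <- noncg_motif_profile(filter(cohort$calls, cell_id %in% keep), assignment)
glance(mp)
#> # A tibble: 1 × 3
#>   n_groups ch_fraction_min ch_fraction_max
#>      <int>           <dbl>           <dbl>
#> 1        6         0.00759          0.0116
```

All 40 cells pass QC (no low-coverage or somatic cells were planted in
this cohort). Cells spread over the full G1–G7 range because the latent
progression is uniform; every one of the 10 planted 100-kbp tiles gets
a defined score, and the gene category is ~2× over-represented in the
fast class — the planted genic-faster-than-intergenic signal. The CH
methylated-call fraction sits at 0.8–1.2% per group, far below CpG
levels, concentrated in CAC/CAG motifs.

`run_pipeline("config.yaml", stages = "all")` drives the same stages
from a YAML config and writes one TSV per result (`qc_cells.tsv`,
`cell_levels.tsv`, `tile_means.tsv`, `tile_kinetics.bed`,
`enrichment.tsv`, `gene_kinetics.tsv`, `context_profile.tsv`,
`masked_means.tsv`, `tertile_tests.tsv`, `motif_profile.tsv`).

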