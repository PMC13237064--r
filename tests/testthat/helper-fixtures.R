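# Shared synthetic fixtures (built once per test run) and brute-force
# oracles used to cross-check the statistical machinery.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 1 Mb cohort with somatic contamination and mitotic cells: QC, grouping,
# context and motif tests
toy_genome <- function() memo("toy_genome", function() {
  build_genome(genome_config(chrom_sizes = c(chr1 = 1e6), n_genes = 10,
                             n_line = 8, n_ltr = 5, seed = 101))
})

toy_cohort <- function() memo("toy_cohort", function() {
  simulate_cells(toy_genome(),
                 kinetic_model(seed = 102, somatic_fraction = 0.05),
                 n_cells = 50, coverage_fraction = 0.2,
                 ch_coverage_fraction = 0.02, lambda_calls = 2000)
})

toy_fixture_dir <- function() memo("toy_fixture_dir", function() {
  d <- file.path(tempdir(), "scmethkin-toy-fixture")
  emit_fixture(toy_cohort(), d)
  d
})

# 2 Mb, 60-cell, CpG-only cohort with planted tile classes: kinetics
kin_genome <- function() memo("kin_genome", function() {
  build_genome(genome_config(chrom_sizes = c(chr1 = 2e6), n_genes = 20,
                             seed = 11))
})

kin_cohort <- function() memo("kin_cohort", function() {
  simulate_cells(kin_genome(),
                 kinetic_model(seed = 12, somatic_fraction = 0),
                 n_cells = 60, coverage_fraction = 0.2,
                 ch_coverage_fraction = 0, lambda_calls = 2000)
})

kin_groups <- function() memo("kin_groups", function() {
  assign_groups(cell_methylation_levels(kin_cohort()$cpg),
                group_scheme("marmoset"))
})

# 1 Mb cohort whose genes are spread evenly over the kinetic classes:
# gene-level class recovery and planted accessibility ordering
acc_cohort <- function() memo("acc_cohort", function() {
  g <- build_genome(genome_config(chrom_sizes = c(chr1 = 1.2e6), n_genes = 12,
                                  gene_class_weights = c(fast = 1,
                                                         intermediate = 1,
                                                         slow = 1),
                                  n_line = 6, n_ltr = 4, seed = 111))
  simulate_cells(g, kinetic_model(seed = 112, somatic_fraction = 0),
                 n_cells = 40, coverage_fraction = 0.2,
                 ch_coverage_fraction = 0, lambda_calls = 1000)
})

# small cohort with perfect conversion: motif-weight recovery, active
# regions strictly unmethylated
pure_cohort <- function() memo("pure_cohort", function() {
  g <- build_genome(genome_config(chrom_sizes = c(chr1 = 3e5), n_genes = 4,
                                  n_line = 3, n_ltr = 2, n_orphan_cgi = 2,
                                  seed = 201))
  simulate_cells(g, kinetic_model(seed = 202, conversion_rate = 1,
                                  somatic_fraction = 0),
                 n_cells = 10, coverage_fraction = 0.3,
                 ch_coverage_fraction = 0.25, lambda_calls = 1000)
})

# hand-built merged dyad table: cell_id/chrom/pos/n_meth/n_unmeth
dyads_tbl <- function(pos, n_meth, n_unmeth, cell_id = "c1", chrom = "chr1") {
  tibble::tibble(cell_id = cell_id, chrom = chrom, pos = pos,
                 n_meth = n_meth, n_unmeth = n_unmeth)
}

# ---- brute-force oracles -------------------------------------------

# Benjamini-Hochberg step-up, directly from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# Pearson chi-squared from the expected-count formula
chisq_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# union footprint length by per-bp scan
union_len_brute <- function(tbl, chrom_len) {
  covered <- logical(chrom_len)
  for (i in seq_len(nrow(tbl))) {
    covered[(tbl$start[i] + 1):tbl$end[i]] <- TRUE
  }
  sum(covered)
}

# expected observed methylation (conversion-inflated true level)
observed_level <- function(m, conversion) m + (1 - m) * (1 - conversion)
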