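# Synthetic genome and cohort generator: structural invariants,
# determinism, and recovery of the generator's own parameters.

test_that("genome has the requested gene count, promoters upstream, and valid intervals", {
  g <- toy_genome()
  gm <- g$gene_models
  expect_equal(nrow(gm), 10)
  expect_true(all(gm$promoter_end == gm$start))
  expect_true(all(gm$promoter_start < gm$promoter_end))
  ann <- g$annotations
  expect_true(all(ann$start < ann$end))
  sizes <- g$chrom_sizes[ann$chrom]
  expect_true(all(ann$start >= 0 & ann$end <= sizes))
  # exons sit inside their gene body
  ex <- ann[ann$category == "exon", ]
  body <- gm[match(ex$name, gm$gene_id), ]
  expect_true(all(ex$start >= body$start & ex$end <= body$end))
  # lambda carries no annotation
  expect_false(g$lambda_contig %in% ann$chrom)
})

test_that("every genomic bp belongs to at least one structural category", {
  g <- toy_genome()
  structural <- g$annotations[g$annotations$category %in%
                                c("exon", "intron", "promoter", "flanking",
                                  "intergenic"), ]
  covered <- union_len_brute(structural, g$chrom_sizes[["chr1"]])
  expect_equal(covered, unname(g$chrom_sizes[["chr1"]]))
})

test_that("genome build is deterministic: same seed gives byte-identical outputs", {
  cfg <- genome_config(chrom_sizes = c(chr1 = 3e5), n_genes = 4, n_line = 3,
                       n_ltr = 2, n_orphan_cgi = 2, seed = 7)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    dir.create(d, showWarnings = FALSE)
    g <- build_genome(cfg)
    write_genome_fasta(g, file.path(d, "g.fa"))
    write_annotation_beds(g, file.path(d, "beds"))
  }
  expect_identical(unname(tools::md5sum(file.path(d1, "g.fa"))),
                   unname(tools::md5sum(file.path(d2, "g.fa"))))
  b1 <- list.files(file.path(d1, "beds"), full.names = TRUE)
  b2 <- file.path(d2, "beds", basename(b1))
  expect_identical(unname(tools::md5sum(b1)), unname(tools::md5sum(b2)))
})

test_that("CpG density inside CpG islands exceeds background, by direct count", {
  g <- toy_genome()
  s <- g$sequence[["chr1"]]
  cg_pos <- as.integer(gregexpr("CG", s, fixed = TRUE)[[1]])
  cgi <- g$annotations[g$annotations$category == "cgi", ]
  inside <- rep(FALSE, length(cg_pos))
  for (i in seq_len(nrow(cgi))) {
    inside <- inside | (cg_pos > cgi$start[i] & cg_pos <= cgi$end[i])
  }
  cgi_bp <- union_len_brute(cgi, g$chrom_sizes[["chr1"]])
  dens_in <- sum(inside) / cgi_bp
  dens_out <- sum(!inside) / (g$chrom_sizes[["chr1"]] - cgi_bp)
  expect_gt(dens_in, dens_out)
  expect_gt(dens_in, 0.08)   # planted 0.12 per dyad start
  expect_lt(dens_out, 0.04)  # planted 0.02
})

test_that("overfull configurations raise a capacity error", {
  cfg <- genome_config(chrom_sizes = c(chr1 = 2e5), n_genes = 40,
                       gene_length_range = c(2e4, 3e4), seed = 1)
  expect_error(build_genome(cfg), "capacity")
})

test_that("expected global methylation is monotone non-decreasing in tau", {
  g <- toy_genome()
  m <- kinetic_model()
  taus <- seq(0, 1, by = 0.05)
  ex <- expected_global_methylation(g, m, taus)
  expect_true(all(diff(ex) >= -1e-12))
  for (cl in c("fast", "intermediate", "slow")) {
    expect_true(all(diff(expected_methylation(m, cl, taus)) >= -1e-12))
  }
  # fast gains more than slow early on
  expect_gt(expected_methylation(m, "fast", 0.3),
            expected_methylation(m, "slow", 0.3))
})

test_that("perfect conversion and tau=0 give only unmethylated calls", {
  g <- pure_cohort()$genome
  plan <- tibble::tibble(cell_id = "t0", tau = 0, type = "germ")
  co <- simulate_cells(g, kinetic_model(seed = 5, conversion_rate = 1),
                       cell_plan = plan, coverage_fraction = 0.2,
                       ch_coverage_fraction = 0, lambda_calls = 500)
  expect_equal(sum(co$calls$n_meth), 0)
})

test_that("lambda methylated fraction matches the conversion failure rate", {
  g <- toy_genome()
  plan <- tibble::tibble(cell_id = "lam", tau = 0.5, type = "germ")
  co <- simulate_cells(g, kinetic_model(seed = 6, conversion_rate = 0.99),
                       cell_plan = plan, coverage_fraction = 0.01,
                       ch_coverage_fraction = 0, lambda_calls = 10000)
  lam <- co$calls[co$calls$chrom == g$lambda_contig, ]
  n <- sum(lam$n_meth + lam$n_unmeth)
  frac <- sum(lam$n_meth) / n
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("realized global methylation tracks latent progression (emitted files)", {
  dir <- toy_fixture_dir()
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  truth <- readr::read_tsv(file.path(dir, "truth_cells.tsv"),
                           show_col_types = FALSE)
  germ <- truth[truth$type == "germ", ]
  levels <- vapply(germ$cell_id, function(cid) {
    calls <- read_cytosine_report(
      file.path(dir, sheet$call_file[match(cid, sheet$cell_id)]),
      cell_id = cid)
    global_cpg_methylation(merge_cpg_strands(calls))
  }, numeric(1))
  expect_gt(stats::cor(germ$tau, levels, method = "spearman"), 0.9)
})

test_that("with c=1 every call inside active regions is unmethylated", {
  co <- pure_cohort()
  ann <- co$genome$annotations
  active <- ann[ann$category %in% c("promoter", "cgi", "atac_peak"), ]
  cg <- co$calls[co$calls$context == "CG" &
                   co$calls$chrom != co$genome$lambda_contig, ]
  dyad_pos <- ifelse(cg$strand == "-", cg$pos - 1L, cg$pos)
  gr_sites <- GenomicRanges::GRanges(cg$chrom,
                                     IRanges::IRanges(dyad_pos, width = 1))
  gr_active <- GenomicRanges::GRanges(active$chrom,
                                      IRanges::IRanges(active$start + 1,
                                                       active$end))
  inside <- IRanges::overlapsAny(gr_sites, gr_active)
  expect_gt(sum(inside), 100)
  expect_equal(sum(cg$n_meth[inside]), 0)
})

test_that("CH methylated-call motifs follow the configured weights (chi-squared GOF)", {
  co <- pure_cohort()
  w <- co$model$ch_motif_weights
  ch <- co$calls[co$calls$context %in% c("CHG", "CHH") &
                   co$calls$chrom != co$genome$lambda_contig, ]
  counts <- tapply(ch$n_meth, ch$trinucleotide, sum)[names(w)]
  counts[is.na(counts)] <- 0
  expect_gt(sum(counts), 500)
  gof <- stats::chisq.test(as.numeric(counts), p = as.numeric(w))
  expect_gt(gof$p.value, 0.01)
})

test_that("parameter validation rejects impossible cohort requests", {
  g <- pure_cohort()$genome
  expect_error(simulate_cells(g, kinetic_model(), n_cells = 0), "n_cells")
  expect_error(simulate_cells(g, kinetic_model(), n_cells = 5,
                              coverage_fraction = 0), "coverage_fraction")
  expect_error(simulate_cells(g, kinetic_model(), n_cells = 5,
                              coverage_fraction = 1.2), "coverage_fraction")
  expect_error(kinetic_model(conversion_rate = 0))
  expect_error(kinetic_model(ch_motif_weights = c(CAC = 1, CAG = 0.5)),
               "sum to 1")
})

test_that("emitted fixture has a complete, reproducible, validatable manifest", {
  g <- build_genome(genome_config(chrom_sizes = c(chr1 = 2.5e5), n_genes = 3,
                                  n_line = 2, n_ltr = 2, n_orphan_cgi = 1,
                                  seed = 31))
  co <- simulate_cells(g, kinetic_model(seed = 32, somatic_fraction = 0),
                       n_cells = 3, coverage_fraction = 0.2,
                       ch_coverage_fraction = 0.02, lambda_calls = 300)
  d1 <- file.path(tempdir(), "fx1")
  m1 <- emit_fixture(co, d1)
  expect_equal(sum(grepl("^cells/", m1$file)), 3)
  expect_true("sample_sheet.tsv" %in% m1$file)
  expect_gte(sum(grepl("^beds/", m1$file)), 1)
  expect_true(validate_manifest(d1))

  d2 <- file.path(tempdir(), "fx2")
  m2 <- emit_fixture(co, d2)
  expect_identical(m1$md5, m2$md5)

  victim <- file.path(d1, m1$file[grepl("^cells/", m1$file)][1])
  unlink(victim)
  expect_error(validate_manifest(d1), basename(victim), fixed = TRUE)
})
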