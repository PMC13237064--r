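# Context profiles, active-region masking, expression tertiles,
# non-CpG motif analysis.

one_group <- function(cells) {
  tibble::tibble(cell_id = cells, level = 0.5,
                 group = factor("G1", levels = "G1"))
}

test_that("a category covering all covered sites equals the genome-wide mean", {
  cpg <- dyads_tbl(pos = c(10L, 20L, 30L), n_meth = c(1L, 0L, 1L),
                   n_unmeth = c(0L, 1L, 1L))
  ann <- tibble::tibble(category = "exon", chrom = "chr1",
                        start = 0L, end = 100L)
  prof <- context_methylation_profile(cpg, one_group("c1"), ann)
  exon <- prof$mean[prof$category == "exon"]
  gw <- prof$mean[prof$category == "genome_wide"]
  expect_equal(exon, gw)
  expect_equal(gw, mean(c(1, 0, 0.5)))
})

test_that("an all-methylated category footprint reports mean 1 and empty ones NA", {
  cpg <- dyads_tbl(pos = c(10L, 50L), n_meth = c(2L, 0L), n_unmeth = c(0L, 3L))
  ann <- tibble::tibble(category = c("cgi", "line"), chrom = "chr1",
                        start = c(0L, 200L), end = c(20L, 300L))
  prof <- context_methylation_profile(cpg, one_group("c1"), ann)
  expect_equal(prof$mean[prof$category == "cgi"], 1.0)
  expect_true(is.na(prof$mean[prof$category == "line"]))
  expect_equal(prof$n[prof$category == "line"], 0L)
})

test_that("context means at the final stage recover the planted exon/intergenic gap", {
  co <- kin_cohort()
  asn <- kin_groups()
  ann <- co$genome$annotations
  prof <- context_methylation_profile(co$cpg, asn, ann)
  top <- prof[prof$group == "G7" & !is.na(prof$mean), ]
  # genic contexts finish higher than intergenic ones (planted kinetics)
  expect_gt(top$mean[top$category == "exon"],
            top$mean[top$category == "intergenic"])
  # closed-form check against the generator for two categories
  dyads <- cpg_dyad_table(co$genome)
  dyads <- dyads[!dyads$lambda, ]
  truth <- co$cell_truth
  cells <- asn$cell_id[asn$group == "G7"]
  taus <- truth$tau[match(cells, truth$cell_id)]
  exp_site <- rowMeans(vapply(taus, function(t) {
    observed_level(true_dyad_levels(dyads, co$model, t),
                   co$model$conversion_rate)
  }, numeric(nrow(dyads))))
  for (cat in c("exon", "intergenic")) {
    sel <- scmethkin:::sites_in_intervals(dyads$chrom, dyads$pos,
                                          ann[ann$category == cat, ])
    expect_lt(abs(top$mean[top$category == cat] - mean(exp_site[sel])), 0.03)
  }
})

test_that("masking arithmetic matches the worked mixture example", {
  # 10 dyads: 4 inside the mask at rate 0, 6 outside at rate 0.8
  cpg <- dyads_tbl(pos = c(5L, 10L, 15L, 20L, 105L, 110L, 115L, 120L, 125L, 130L),
                   n_meth = c(0L, 0L, 0L, 0L, rep(4L, 6)),
                   n_unmeth = c(5L, 5L, 5L, 5L, rep(1L, 6)))
  ann <- tibble::tibble(category = "promoter", chrom = "chr1",
                        start = 0L, end = 30L)
  res <- mask_active_regions(cpg, one_group("c1"), ann, halfwidth = 40)
  expect_equal(res$mean_unmasked, 0.48)
  expect_equal(res$mean_masked, 0.8)
  expect_equal(res$delta, 0.32)
})

test_that("no active elements means no masking delta; total masks error", {
  cpg <- dyads_tbl(pos = c(10L, 20L), n_meth = 1L, n_unmeth = 1L)
  no_active <- tibble::tibble(category = "line", chrom = "chr1",
                              start = 0L, end = 5L)
  res <- mask_active_regions(cpg, one_group("c1"), no_active)
  expect_equal(res$delta, 0)
  expect_equal(res$n_masked, res$n_unmasked)
  everything <- tibble::tibble(category = "promoter", chrom = "chr1",
                               start = 0L, end = 100L)
  expect_error(mask_active_regions(cpg, one_group("c1"), everything,
                                   halfwidth = 1000), "mask covers")
})

test_that("masking delta on the cohort matches the two-component mixture closed form", {
  co <- kin_cohort()
  asn <- kin_groups()
  ann <- co$genome$annotations
  res <- mask_active_regions(co$cpg, asn, ann, halfwidth = 2000)
  # oracle: expected mean over all dyads vs dyads outside the mask
  dyads <- cpg_dyad_table(co$genome)
  dyads <- dyads[!dyads$lambda, ]
  mask <- active_region_mask(ann, halfwidth = 2000)
  out_mask <- !scmethkin:::sites_in_intervals(dyads$chrom, dyads$pos, mask)
  truth <- co$cell_truth
  for (g in c("G5", "G7")) {
    cells <- asn$cell_id[asn$group == g]
    taus <- truth$tau[match(cells, truth$cell_id)]
    exp_site <- rowMeans(vapply(taus, function(t) {
      observed_level(true_dyad_levels(dyads, co$model, t),
                     co$model$conversion_rate)
    }, numeric(nrow(dyads))))
    want_delta <- mean(exp_site[out_mask]) - mean(exp_site)
    got <- res[res$group == g, ]
    expect_gt(got$delta, 0)
    expect_lt(abs(got$delta - want_delta), 0.02)
  }
})

test_that("low-CpG promoters are dropped by the observed/expected filter", {
  g <- toy_genome()
  ann <- filter_low_cpg_promoters(g$annotations, g, ratio = 0.4)
  n_before <- sum(g$annotations$category == "promoter")
  n_after <- sum(ann$category == "promoter")
  # CGI-bearing promoters survive; promoters at background density do not
  expect_lt(n_after, n_before)
  expect_gt(n_after, 0)
  expect_equal(sum(ann$category == "cgi"),
               sum(g$annotations$category == "cgi"))
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               rep(0.03, 3))
  set.seed(123)
  for (i in 1:100) {
    p <- stats::runif(sample(3:12, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("identical methylation distributions are not called different", {
  set.seed(1)
  vals <- stats::runif(12)
  p <- stats::wilcox.test(vals, vals, exact = FALSE)$p.value
  expect_gt(p, 0.9)
})

test_that("expression tertiles split evenly and detect the planted coupling", {
  co <- kin_cohort()
  asn <- kin_groups()
  tc <- expression_tertile_analysis(co$expression, co$cpg, asn,
                                    co$genome$gene_models, min_sites = 10)
  sizes <- table(tc$tertiles$tertile)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_true(all(tc$tests$q_value >= tc$tests$p_value - 1e-12))
  # high-expression genes sit in fast tiles: in mid groups their gene-body
  # methylation runs ahead of the low tertile
  mid <- tc$tests[tc$tests$group %in% c("G3", "G4", "G5") &
                    tc$tests$pair == "high_vs_low", ]
  expect_gt(nrow(mid), 0)
  expect_true(any(mid$q_value < 0.05))
  meth_mid <- tc$methylation[tc$methylation$group %in% c("G3", "G4"), ]
  med <- tapply(meth_mid$mean, meth_mid$tertile, stats::median)
  expect_gt(med[["high"]], med[["low"]])
})

test_that("motif fractions follow their definitions on hand-built calls", {
  mk_calls <- function(n, n_pos, trinuc, ctx) {
    meth_col <- rep(c(1L, 0L), c(n_pos, n - n_pos))
    tibble::tibble(cell_id = "c1", chrom = "chr1", pos = seq_len(n),
                   strand = "+", context = ctx, trinucleotide = trinuc,
                   n_meth = meth_col, n_unmeth = 1L - meth_col)
  }
  calls <- dplyr::bind_rows(
    mk_calls(1000, 10, "CAC", "CHH"),
    mk_calls(100, 50, "CGA", "CG"))
  mp <- noncg_motif_profile(calls, one_group("c1"))
  ch <- mp$fractions[mp$fractions$context == "CH", ]
  expect_equal(ch$fraction, 0.01)
  cg <- mp$fractions[mp$fractions$context == "CG", ]
  expect_equal(cg$fraction, 0.5)
  # all methylated CH calls in CAC: CAN share 100%, CAC share 100%
  motif_ch <- mp$motifs[mp$motifs$context_class == "CH", ]
  expect_equal(motif_ch$share[motif_ch$trinucleotide == "CAC"], 1)
  # shares sum to one per group and class
  sums <- tapply(mp$motifs$share,
                 paste(mp$motifs$group, mp$motifs$context_class), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("recovered CH motif shares match the planted weights within 3 SD", {
  co <- pure_cohort()
  asn <- assign_groups(cell_methylation_levels(co$cpg),
                       group_scheme("marmoset"))
  mp <- noncg_motif_profile(co$calls, asn)
  pooled <- mp$motifs[mp$motifs$context_class == "CH", ] |>
    dplyr::summarise(n_meth = sum(.data$n_meth), .by = "trinucleotide")
  total <- sum(pooled$n_meth)
  w <- co$model$ch_motif_weights
  expect_gt(total, 500)
  for (m in names(w)) {
    share <- pooled$n_meth[pooled$trinucleotide == m] / total
    if (length(share) == 0) share <- 0
    expect_lt(abs(share - w[[m]]),
              3 * sqrt(w[[m]] * (1 - w[[m]]) / total) + 1e-9)
  }
})

test_that("site mode binarizes coverage before counting", {
  calls <- tibble::tibble(cell_id = "c1", chrom = "chr1", pos = 1:2,
                          strand = "+", context = "CHH",
                          trinucleotide = "CAC",
                          n_meth = c(3L, 0L), n_unmeth = c(1L, 4L))
  mp <- noncg_motif_profile(calls, one_group("c1"), mode = "site")
  ch <- mp$fractions[mp$fractions$context == "CH", ]
  expect_equal(ch$fraction, 0.5)  # one of two sites methylated
})
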