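# Tiling, group means, kinetic score S, fast/intermediate/slow classes,
# enrichment, gene-body kinetics.

test_that("tiling truncates the last tile and validates tile_size", {
  tiles <- tile_genome(c(chrA = 1234567), 5e5)
  expect_equal(nrow(tiles), 3)
  expect_equal(tiles$end - tiles$start, c(5e5, 5e5, 234567))
  expect_error(tile_genome(c(chrA = 100), 0), "positive")
})

# small hand-built cohort: 4 cells in 4 groups, one dyad rate per cell
mini_assignment <- tibble::tibble(
  cell_id = c("a", "b", "x", "y"), level = c(0.05, 0.25, 0.45, 0.65),
  group = factor(c("G1", "G3", "G5", "G7"), levels = paste0("G", 1:7)))

test_that("pooled tile means weight every dyad observation equally", {
  cpg <- dplyr::bind_rows(
    dyads_tbl(pos = 1:2, n_meth = c(1L, 1L), n_unmeth = c(0L, 0L), cell_id = "a"),
    dyads_tbl(pos = 1:2, n_meth = c(0L, 0L), n_unmeth = c(1L, 1L), cell_id = "b"),
    dyads_tbl(pos = 1L, n_meth = 1L, n_unmeth = 0L, cell_id = "z"))
  asn <- tibble::tibble(cell_id = c("a", "b", "z"), level = c(0.1, 0.2, 0.4),
                        group = factor(c("G1", "G1", "G3"),
                                       levels = c("G1", "G3")))
  tm <- tile_group_means(cpg, asn, c(chr1 = 1000L), tile_size = 1000,
                         min_sites = 1)
  expect_equal(tm$mean[tm$group == "G1"], 0.5)
})

test_that("kinetic score is the early gain minus the late gain", {
  mk_tm <- function(g1, g3, g5, g7) {
    tibble::tibble(tile_id = "t", chrom = "chr1", start = 0L, end = 1000L,
                   group = factor(paste0("G", c(1, 3, 5, 7))),
                   mean = c(g1, g3, g5, g7), n = 100L)
  }
  s1 <- kinetic_score(mk_tm(0.05, 0.25, 0.45, 0.50))
  expect_equal(s1$score, 0.15)
  s2 <- kinetic_score(mk_tm(0.02, 0.08, 0.30, 0.60))
  expect_equal(s2$score, -0.24)
  expect_error(kinetic_score(mk_tm(0, 0, 0, 0), early_pair = c("G1", "G5"),
                             late_pair = c("G5", "G7")), "share")
})

test_that("S is shift-invariant and tertiles are monotone-transform-invariant", {
  co <- kin_cohort()
  tm <- tile_group_means(co$cpg, kin_groups(), co$genome$chrom_sizes,
                         tile_size = 1e5, min_sites = 50)
  tk <- kinetic_score(tm)
  shifted <- tm
  shifted$mean <- shifted$mean + 0.123
  tk2 <- kinetic_score(shifted)
  expect_equal(tk2$score, tk$score, tolerance = 1e-12)

  c1 <- classify_kinetics(tk)
  tk3 <- tk
  tk3$score <- exp(3 * tk3$score)  # strictly monotone transform
  c2 <- classify_kinetics(tk3)
  expect_equal(c1$class, c2$class)
  # classified tiles = tiles with defined S
  expect_equal(sum(c1$class != "unclassified"), sum(!is.na(tk$score)))
})

test_that("planted tile classes are recovered by the tertile rule", {
  co <- kin_cohort()
  tm <- tile_group_means(co$cpg, kin_groups(), co$genome$chrom_sizes,
                         tile_size = 1e5, min_sites = 50)
  tk <- classify_kinetics(kinetic_score(tm))
  cmp <- dplyr::inner_join(
    tibble::as_tibble(tk)[, c("tile_id", "class")],
    co$genome$tiles[, c("tile_id", "class")],
    by = "tile_id", suffix = c("_called", "_planted"))
  expect_gte(mean(cmp$class_called == cmp$class_planted), 0.9)
})

test_that("tile group means match the generator's closed-form expectation", {
  co <- kin_cohort()
  asn <- kin_groups()
  tm <- tile_group_means(co$cpg, asn, co$genome$chrom_sizes,
                         tile_size = 1e5, min_sites = 50)
  dyads <- cpg_dyad_table(co$genome)
  dyads <- dyads[!dyads$lambda, ]
  tile_of <- paste0(dyads$chrom, ":", (dyads$pos - 1L) %/% 1e5)
  truth <- co$cell_truth
  for (g in c("G2", "G6")) {
    cells <- asn$cell_id[asn$group == g]
    taus <- truth$tau[match(cells, truth$cell_id)]
    exp_site <- rowMeans(vapply(taus, function(t) {
      observed_level(true_dyad_levels(dyads, co$model, t),
                     co$model$conversion_rate)
    }, numeric(nrow(dyads))))
    exp_tile <- tapply(exp_site, tile_of, mean)
    got <- tm[tm$group == g & !is.na(tm$mean), ]
    key <- paste0(got$chrom, ":", got$start %/% 1e5)
    expect_gt(nrow(got), 10)
    expect_lt(max(abs(got$mean - exp_tile[key])), 0.03)
  }
})

test_that("chi-squared enrichment matches the closed-form statistic", {
  # textbook 2x2: {{10,90},{30,70}} -> X^2 = 12.5
  tab <- rbind(c(10, 30), c(90, 70))
  expect_equal(unname(stats::chisq.test(tab, correct = FALSE)$statistic), 12.5)
  set.seed(99)
  for (i in 1:100) {
    tab <- matrix(rpois(6, lambda = 60) + 5L, nrow = 2)
    got <- stats::chisq.test(tab, correct = FALSE)
    want <- chisq_brute(tab)
    expect_equal(unname(got$statistic), want$statistic, tolerance = 1e-12)
    expect_equal(unname(got$parameter), want$df)
    expect_equal(got$p.value, want$p_value, tolerance = 1e-12)
  }
})

test_that("identical overlap fractions across classes give statistic 0, p 1", {
  tk <- tibble::tibble(
    tile_id = paste0("t", 1:3), chrom = "chr1",
    start = c(0L, 1000L, 2000L), end = c(1000L, 2000L, 3000L),
    score = c(-0.2, 0, 0.2), class = c("slow", "intermediate", "fast"))
  # the first half of every tile is "genic"
  ann <- tibble::tibble(category = "gene", chrom = "chr1",
                        start = c(0L, 1000L, 2000L),
                        end = c(500L, 1500L, 2500L))
  enr <- annotation_enrichment(tk, ann)
  expect_equal(unique(enr$statistic), 0)
  expect_equal(unique(enr$p_value), 1)
  expect_equal(enr$ratio, rep(1, 3))
})

test_that("planted genic bias is detected as fast-class enrichment", {
  co <- kin_cohort()
  tm <- tile_group_means(co$cpg, kin_groups(), co$genome$chrom_sizes,
                         tile_size = 1e5, min_sites = 50)
  tk <- classify_kinetics(kinetic_score(tm))
  genes <- co$genome$annotations[co$genome$annotations$category == "gene", ]
  enr <- annotation_enrichment(tk, genes)
  fast <- enr[enr$class == "fast", ]
  expect_gt(fast$ratio, 1)
  expect_lt(fast$p_value, 0.05)
  # expected totals add to observed totals
  expect_equal(sum(enr$expected_bp), sum(enr$observed_bp), tolerance = 1e-6)
})

test_that("a gene spanning one uniformly covered tile reproduces the tile score", {
  cells <- paste0("c", 1:4)
  rates <- c(0.05, 0.25, 0.45, 0.50)
  cpg <- purrr::map2_dfr(cells, rates, function(cid, r) {
    n <- 100
    dyads_tbl(pos = seq(5, 995, by = 10), cell_id = cid,
              n_meth = rep(c(1L, 0L), round(c(n * r, n * (1 - r)))),
              n_unmeth = rep(c(0L, 1L), round(c(n * r, n * (1 - r)))))
  })
  asn <- tibble::tibble(cell_id = cells, level = rates,
                        group = factor(paste0("G", c(1, 3, 5, 7))))
  tm <- tile_group_means(cpg, asn, c(chr1 = 1000L), tile_size = 1000,
                         min_sites = 10)
  tile_S <- kinetic_score(tm)$score
  gm <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L, end = 1000L,
                       promoter_start = 0L, promoter_end = 1L)
  gk <- gene_body_kinetics(cpg, asn, gm, atac_peaks = NULL, min_sites = 10)
  expect_equal(gk$score, tile_S)
  expect_equal(gk$accessibility, 0)  # no peaks at all
  expect_error(gene_body_kinetics(cpg, asn,
                                  dplyr::mutate(gm, end = start), NULL),
               "zero-length")
})

test_that("promoter accessibility of recovered gene classes is ordered fast > intermediate > slow", {
  co <- acc_cohort()
  asn <- assign_groups(cell_methylation_levels(co$cpg),
                       group_scheme("marmoset"))
  peaks <- co$genome$annotations[co$genome$annotations$category == "atac_peak", ]
  gk <- gene_body_kinetics(co$cpg, asn, co$genome$gene_models,
                           peaks, min_sites = 20)
  med <- tapply(gk$accessibility[gk$class != "unclassified"],
                gk$class[gk$class != "unclassified"], stats::median)
  expect_gt(med[["fast"]], med[["intermediate"]])
  expect_gt(med[["intermediate"]], med[["slow"]])
})
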