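# Genome tiling, group-average methylation per tile, the kinetic score
# S = (early gain) - (late gain), fast/intermediate/slow classification,
# annotation enrichment, and the gene-body variant.

#' Partition a genome into fixed-size tiles
#'
#' @param chrom_sizes named contig lengths (exclude the spike-in).
#' @param tile_size bp per tile (default 500 kbp); the last tile of each
#'   chromosome is truncated.
#' @return tibble: tile_id, chrom, start, end (0-based half-open).
#' @export
tile_genome <- function(chrom_sizes, tile_size = 5e5) {
  if (tile_size <= 0) abort_param("tile_size must be positive")
  purrr::imap_dfr(as.list(chrom_sizes), function(L, chrom) {
    starts <- seq(0, L - 1, by = tile_size)
    tibble::tibble(chrom = chrom, start = as.integer(starts),
                   end = as.integer(pmin(starts + tile_size, L)))
  }) |>
    dplyr::mutate(tile_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end),
                  .before = 1)
}

#' Group-average methylation per genome tile
#'
#' For every tile and methylation group, the mean methylation over all
#' covered dyad-cell observations of the group's member cells. By
#' default every observation is weighted equally (pooled); with
#' `equal_cell_weight` each cell contributes its within-tile mean.
#' Tile-group combinations with fewer than `min_sites` observations are
#' marked undefined (NA mean).
#'
#' @param cpg strand-merged dyad tibble for the cohort (cell_id, chrom,
#'   pos, n_meth, n_unmeth).
#' @param assignment tibble from [assign_groups()].
#' @param chrom_sizes named contig lengths (spike-in excluded).
#' @param tile_size bp per tile.
#' @param min_sites minimum observations for a defined mean.
#' @param equal_cell_weight average per-cell means instead of pooling.
#' @return tibble of class `tile_means`: tile_id, chrom, start, end,
#'   group, mean, n.
#' @export
tile_group_means <- function(cpg, assignment, chrom_sizes, tile_size = 5e5,
                             min_sites = 50, equal_cell_weight = FALSE) {
  if (tile_size <= 0) abort_param("tile_size must be positive")
  if (dplyr::n_distinct(assignment$group[!is.na(assignment$group)]) < 2) {
    abort_param("need at least two nonempty groups")
  }
  tiles <- tile_genome(chrom_sizes, tile_size)
  obs <- cpg |>
    dplyr::filter(.data$chrom %in% names(chrom_sizes)) |>
    dplyr::inner_join(assignment[, c("cell_id", "group")], by = "cell_id") |>
    dplyr::mutate(
      tile_start = as.integer(((.data$pos - 1L) %/% tile_size) * tile_size),
      rate = dyad_rate(.data$n_meth, .data$n_unmeth)
    )
  agg <- if (equal_cell_weight) {
    obs |>
      dplyr::summarise(rate = mean(.data$rate), n = dplyr::n(),
                       .by = c("chrom", "tile_start", "group", "cell_id")) |>
      dplyr::summarise(mean = mean(.data$rate), n = sum(.data$n),
                       .by = c("chrom", "tile_start", "group"))
  } else {
    obs |>
      dplyr::summarise(mean = mean(.data$rate), n = dplyr::n(),
                       .by = c("chrom", "tile_start", "group"))
  }
  out <- tidyr::expand_grid(tiles,
                            group = factor(levels(assignment$group),
                                           levels = levels(assignment$group))) |>
    dplyr::left_join(agg, by = c("chrom", "start" = "tile_start", "group")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  mean = ifelse(.data$n >= min_sites, .data$mean, NA_real_))
  class(out) <- c("tile_means", class(out))
  attr(out, "min_sites") <- min_sites
  out
}

#' Scoring group pairs per species preset
#'
#' Early and late (lo, hi) group labels used in the kinetic score:
#' marmoset and human compare (G3 - G1) against (G7 - G5); cynomolgus,
#' with five data-driven groups, compares (G2 - G1) against (G5 - G3).
#'
#' @param species "marmoset", "human" or "cynomolgus".
#' @return list with `early` and `late` (lo, hi) label pairs.
#' @export
scoring_pairs <- function(species = "marmoset") {
  switch(species,
         marmoset = ,
         human = list(early = c("G1", "G3"), late = c("G5", "G7")),
         cynomolgus = list(early = c("G1", "G2"), late = c("G3", "G5")),
         abort_param(paste0("unknown species preset: ", species)))
}

#' Kinetic score per tile
#'
#' S = (m_hi_early - m_lo_early) - (m_hi_late - m_lo_late): the
#' methylation gained over the early phase minus the gain over the late
#' phase. Positive scores mark regions acquiring methylation fast
#' (early), negative scores slow (late) regions. S is a pure difference
#' of differences, so it is invariant under adding a constant to all
#' four group means. Defined only where all four group means are
#' defined.
#'
#' @param tm `tile_means` tibble (or the gene analogue).
#' @param early_pair,late_pair (lo, hi) group labels; the two pairs must
#'   not share a label.
#' @return tibble of class `tile_kinetics`: tile_id, chrom, start, end,
#'   early_diff, late_diff, score.
#' @export
kinetic_score <- function(tm, early_pair = c("G1", "G3"),
                          late_pair = c("G5", "G7")) {
  if (length(intersect(early_pair, late_pair)) > 0) {
    abort_param("early and late scoring pairs must not share a group label")
  }
  need <- c(early_pair, late_pair)
  if (!all(need %in% as.character(unique(tm$group)))) {
    abort_param("scoring groups absent from the means table")
  }
  wide <- tm |>
    dplyr::filter(.data$group %in% need) |>
    dplyr::select(dplyr::any_of(c("tile_id", "gene_id")), "chrom", "start",
                  "end", "group", "mean") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean")
  out <- wide |>
    dplyr::mutate(
      early_diff = .data[[early_pair[2]]] - .data[[early_pair[1]]],
      late_diff = .data[[late_pair[2]]] - .data[[late_pair[1]]],
      score = .data$early_diff - .data$late_diff
    ) |>
    dplyr::select(-dplyr::all_of(need))
  class(out) <- c("tile_kinetics", class(out))
  out
}

#' Classify tiles as fast / intermediate / slow
#'
#' Tertile rule (default): tiles with a defined score are split into
#' ascending thirds of S — slow, intermediate, fast (remainder tiles go
#' to the lower classes first; the split depends only on the ranks of S,
#' so any strictly monotone transform of S gives the same classes).
#' Threshold rule: slow iff S < -t, fast iff S > t, intermediate
#' otherwise. Undefined scores are "unclassified".
#'
#' @param tk `tile_kinetics` tibble from [kinetic_score()].
#' @param rule "tertile" or "threshold".
#' @param threshold t for the threshold rule.
#' @return `tk` with a `class` column
#'   (fast/intermediate/slow/unclassified).
#' @export
classify_kinetics <- function(tk, rule = c("tertile", "threshold"),
                              threshold = 0.05) {
  rule <- match.arg(rule)
  cls <- rep("unclassified", nrow(tk))
  def <- which(!is.na(tk$score))
  if (rule == "tertile") {
    sizes <- tertile_sizes(length(def))
    ord <- def[order(tk$score[def])]
    cls[ord] <- rep(c("slow", "intermediate", "fast"), times = sizes)
  } else {
    cls[def] <- dplyr::case_when(
      tk$score[def] < -threshold ~ "slow",
      tk$score[def] > threshold ~ "fast",
      TRUE ~ "intermediate"
    )
  }
  tk$class <- cls
  tk
}

#' Annotation enrichment across kinetic classes
#'
#' For each annotation category, a chi-squared test (df = number of
#' classes - 1) on the contingency of (bp overlapping the category, bp
#' not overlapping) x kinetic class, over classified tiles. The
#' enrichment ratio is the class's overlap fraction divided by the
#' overlap fraction of all classified tiles. When any expected cell is
#' below 5 the p-value falls back to a Monte Carlo estimate (recorded in
#' the `method` column).
#'
#' @param tk classified `tile_kinetics`.
#' @param annotations interval tibble (category/chrom/start/end).
#' @param alpha significance level for the `significant` flag.
#' @param seed seed for the Monte Carlo fallback.
#' @return tibble: category, class, observed_bp, total_bp, expected_bp,
#'   ratio, statistic, df, p_value, method, significant.
#' @export
annotation_enrichment <- function(tk, annotations, alpha = 0.05, seed = 1) {
  classed <- tk[tk$class != "unclassified", ]
  classes <- sort(unique(classed$class))
  if (length(classes) < 2) abort_param("need at least two nonempty classes")
  purrr::map_dfr(sort(unique(annotations$category)), function(cat) {
    ann <- annotations[annotations$category == cat, ]
    per_class <- purrr::map_dfr(classes, function(cl) {
      tiles <- classed[classed$class == cl, ]
      total <- sum(tiles$end - tiles$start)
      ov <- overlap_bp(tiles, ann)
      tibble::tibble(class = cl, observed_bp = ov, total_bp = total)
    })
    tab <- rbind(per_class$observed_bp,
                 per_class$total_bp - per_class$observed_bp)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (min(expected) < 5) {
      warning("expected count < 5 for category ", cat,
              "; using Monte Carlo p-value", call. = FALSE)
      set.seed(seed)
      ht <- stats::chisq.test(tab, simulate.p.value = TRUE, B = 2000)
      method <- "chi-squared (Monte Carlo)"
      df <- length(classes) - 1
    } else {
      ht <- stats::chisq.test(tab, correct = FALSE)
      method <- "chi-squared"
      df <- unname(ht$parameter)
    }
    overall <- sum(per_class$observed_bp) / sum(per_class$total_bp)
    per_class |>
      dplyr::mutate(
        category = cat,
        expected_bp = expected[1, ],
        ratio = (.data$observed_bp / .data$total_bp) / overall,
        statistic = unname(ht$statistic),
        df = df,
        p_value = ht$p.value,
        method = method,
        significant = ht$p.value < alpha,
        .before = 1
      ) |>
      dplyr::relocate("category")
  })
}

#' Gene-body methylation kinetics and promoter accessibility
#'
#' Per gene: group-mean methylation over the gene body, the kinetic
#' score S (as for tiles), a tertile class among scored genes, and a
#' promoter accessibility score = total ATAC-peak bp overlapping the
#' promoter, weighted by the peak signal column when present.
#'
#' @param cpg cohort merged dyad tibble.
#' @param assignment tibble from [assign_groups()].
#' @param gene_models tibble with gene_id, chrom, start, end,
#'   promoter_start, promoter_end.
#' @param atac_peaks interval tibble (chrom/start/end, optional score);
#'   NULL for no accessibility column.
#' @param early_pair,late_pair scoring pairs, as for [kinetic_score()].
#' @param min_sites minimum observations per gene-group mean.
#' @param signal_weight weight promoter overlap by the peak score.
#' @return tibble: gene_id, chrom, start, end, early_diff, late_diff,
#'   score, class, accessibility.
#' @export
gene_body_kinetics <- function(cpg, assignment, gene_models, atac_peaks = NULL,
                               early_pair = c("G1", "G3"),
                               late_pair = c("G5", "G7"),
                               min_sites = 20, signal_weight = TRUE) {
  if (any(gene_models$end <= gene_models$start)) {
    abort_param("gene with zero-length body in gene_models")
  }
  obs <- cpg |>
    dplyr::inner_join(assignment[, c("cell_id", "group")], by = "cell_id") |>
    dplyr::mutate(rate = dyad_rate(.data$n_meth, .data$n_unmeth))
  site_gr <- sites_to_gr(obs$chrom, obs$pos)
  gene_gr <- intervals_to_gr(gene_models)
  hits <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  mapped <- obs[S4Vectors::queryHits(hits), ] |>
    dplyr::mutate(gene_id = gene_models$gene_id[S4Vectors::subjectHits(hits)])
  means <- mapped |>
    dplyr::summarise(mean = mean(.data$rate), n = dplyr::n(),
                     .by = c("gene_id", "group")) |>
    dplyr::mutate(mean = ifelse(.data$n >= min_sites, .data$mean, NA_real_))
  full <- tidyr::expand_grid(
    gene_models[, c("gene_id", "chrom", "start", "end")],
    group = factor(levels(assignment$group), levels = levels(assignment$group))) |>
    dplyr::left_join(means, by = c("gene_id", "group")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  gk <- kinetic_score(full, early_pair, late_pair) |>
    classify_kinetics(rule = "tertile")
  gk$accessibility <- promoter_accessibility(gene_models, atac_peaks,
                                             signal_weight)
  class(gk) <- setdiff(class(gk), "tile_kinetics")
  class(gk) <- c("gene_kinetics", class(gk))
  gk
}

promoter_accessibility <- function(gene_models, atac_peaks, signal_weight = TRUE) {
  if (is.null(atac_peaks) || nrow(atac_peaks) == 0) {
    return(rep(0, nrow(gene_models)))
  }
  prom <- gene_models |>
    dplyr::transmute(chrom = .data$chrom, start = .data$promoter_start,
                     end = .data$promoter_end)
  prom_gr <- intervals_to_gr(prom)
  peak_gr <- intervals_to_gr(atac_peaks)
  hits <- GenomicRanges::findOverlaps(prom_gr, peak_gr)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(prom_gr)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(peak_gr)[S4Vectors::subjectHits(hits)]))
  w <- if (signal_weight && "score" %in% names(atac_peaks) &&
             !all(is.na(atac_peaks$score))) {
    atac_peaks$score[S4Vectors::subjectHits(hits)]
  } else rep(1, length(hits))
  acc <- rep(0, nrow(gene_models))
  contrib <- tapply(ov * w, S4Vectors::queryHits(hits), sum)
  acc[as.integer(names(contrib))] <- as.numeric(contrib)
  acc
}
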