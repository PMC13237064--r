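# Context-resolved methylation profiles, active-region masking,
# expression-tertile comparisons, and non-CpG motif analysis.

#' Methylation profile across genomic contexts, per group
#'
#' For each annotation category and methylation group, the mean over all
#' covered dyad observations (of the group's member cells) falling
#' inside the category footprint; a dyad inside overlapping categories
#' counts in each. A "genome_wide" meta-category covers every genomic
#' dyad. Categories with zero covered observations in a group are
#' reported with an undefined (NA) mean.
#'
#' @param cpg cohort merged dyad tibble.
#' @param assignment tibble from [assign_groups()].
#' @param annotations interval tibble (category/chrom/start/end).
#' @param lambda_contig spike-in contig, always excluded.
#' @return tibble: category, group, mean, n.
#' @export
context_methylation_profile <- function(cpg, assignment, annotations,
                                        lambda_contig = "lambda") {
  obs <- cpg |>
    dplyr::filter(.data$chrom != lambda_contig) |>
    dplyr::inner_join(assignment[, c("cell_id", "group")], by = "cell_id") |>
    dplyr::mutate(rate = dyad_rate(.data$n_meth, .data$n_unmeth))
  groups <- factor(levels(assignment$group), levels = levels(assignment$group))
  cats <- sort(unique(annotations$category))
  per_cat <- purrr::map_dfr(cats, function(cat) {
    inside <- sites_in_intervals(obs$chrom, obs$pos,
                                 annotations[annotations$category == cat, ])
    obs[inside, ] |>
      dplyr::summarise(mean = mean(.data$rate), n = dplyr::n(), .by = "group") |>
      dplyr::mutate(category = cat, .before = 1)
  })
  gw <- obs |>
    dplyr::summarise(mean = mean(.data$rate), n = dplyr::n(), .by = "group") |>
    dplyr::mutate(category = "genome_wide", .before = 1)
  tidyr::expand_grid(category = c(cats, "genome_wide"), group = groups) |>
    dplyr::left_join(dplyr::bind_rows(per_cat, gw),
                     by = c("category", "group")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Mask intervals around active regulatory elements
#'
#' One mask interval per active element: the element itself unioned with
#' midpoint +/- `halfwidth` bp.
#'
#' @param annotations interval tibble.
#' @param active categories treated as active.
#' @param halfwidth bp on each side of the element midpoint.
#' @return union interval tibble of the mask footprint.
#' @export
active_region_mask <- function(annotations,
                               active = c("promoter", "cgi", "atac_peak"),
                               halfwidth = 2000) {
  el <- annotations[annotations$category %in% active, ]
  if (nrow(el) == 0) return(el[, c("chrom", "start", "end")])
  centered <- el |>
    dplyr::mutate(mid = (.data$start + .data$end) %/% 2L,
                  start = pmin(.data$start, pmax(0L, .data$mid - as.integer(halfwidth))),
                  end = pmax(.data$end, .data$mid + as.integer(halfwidth)))
  union_intervals(centered)
}

#' Genome-wide methylation with active regions masked out
#'
#' Recomputes the per-group genome-wide mean after excluding every dyad
#' within the [active_region_mask()] footprint (active elements plus
#' +/- `halfwidth` around their midpoints), and reports the change
#' relative to the unmasked mean. Active regulatory elements are held
#' unmethylated during establishment, so masking them raises the
#' genome-wide average.
#'
#' @inheritParams context_methylation_profile
#' @param active active categories.
#' @param halfwidth bp on each side of element midpoints.
#' @return tibble: group, n_unmasked, mean_unmasked, n_masked,
#'   mean_masked, delta (masked - unmasked).
#' @export
mask_active_regions <- function(cpg, assignment, annotations,
                                active = c("promoter", "cgi", "atac_peak"),
                                halfwidth = 2000, lambda_contig = "lambda") {
  mask <- active_region_mask(annotations, active, halfwidth)
  obs <- cpg |>
    dplyr::filter(.data$chrom != lambda_contig) |>
    dplyr::inner_join(assignment[, c("cell_id", "group")], by = "cell_id") |>
    dplyr::mutate(rate = dyad_rate(.data$n_meth, .data$n_unmeth),
                  masked_out = sites_in_intervals(.data$chrom, .data$pos, mask))
  if (nrow(obs) > 0 && all(obs$masked_out)) {
    abort_param("mask covers every covered dyad; masked mean undefined")
  }
  obs |>
    dplyr::summarise(
      n_unmasked = dplyr::n(),
      mean_unmasked = mean(.data$rate),
      n_masked = sum(!.data$masked_out),
      mean_masked = mean(.data$rate[!.data$masked_out]),
      .by = "group") |>
    dplyr::mutate(delta = .data$mean_masked - .data$mean_unmasked) |>
    dplyr::arrange(.data$group)
}

#' Drop low-CpG promoters from the promoter category
#'
#' Computes observed/expected CpG within each promoter interval
#' (observed CG dinucleotides over C-count x G-count / length) and
#' removes promoters below `ratio` from the "promoter" category; other
#' categories pass through untouched.
#'
#' @param annotations interval tibble.
#' @param sequences named character vector of contig sequences (or a
#'   `sim_genome`).
#' @param ratio observed/expected CpG cutoff.
#' @return filtered annotation tibble.
#' @export
filter_low_cpg_promoters <- function(annotations, sequences, ratio = 0.4) {
  seqs <- load_sequences(sequences)
  prom <- annotations[annotations$category == "promoter", ]
  if (nrow(prom) == 0) return(annotations)
  oe <- purrr::pmap_dbl(prom, function(chrom, start, end, ...) {
    s <- substring(seqs[[chrom]], start + 1L, end)
    n_c <- stringr::str_count(s, stringr::fixed("C"))
    n_g <- stringr::str_count(s, stringr::fixed("G"))
    n_cg <- stringr::str_count(s, stringr::fixed("CG"))
    expct <- n_c * n_g / nchar(s)
    if (expct == 0) 0 else n_cg / expct
  })
  dplyr::bind_rows(annotations[annotations$category != "promoter", ],
                   prom[oe >= ratio, ])
}

#' Gene-body methylation across expression tertiles
#'
#' Genes are ranked by mean normalized expression across the included
#' cells and split into high/mid/low tertiles (sizes differing by at
#' most one; ties broken by gene id). Per methylation group, gene-body
#' methylation (pooled dyad mean over the group's cells) is compared
#' between every tertile pair with a two-sided Wilcoxon rank-sum test;
#' p-values are Benjamini-Hochberg adjusted across all reported tests.
#'
#' @param expr long expression tibble.
#' @param cpg cohort merged dyad tibble.
#' @param assignment tibble from [assign_groups()].
#' @param gene_models gene interval tibble (gene_id/chrom/start/end).
#' @param min_sites minimum dyad observations for a gene-group mean.
#' @param min_genes minimum genes per tertile for a test.
#' @return list of class `tertile_comparison`: `tertiles` (gene_id,
#'   mean_expr, tertile), `methylation` (gene_id, group, mean, n),
#'   `tests` (group, pair, n_a, n_b, p_value, q_value).
#' @export
expression_tertile_analysis <- function(expr, cpg, assignment, gene_models,
                                        min_sites = 10, min_genes = 3) {
  cells <- assignment$cell_id
  mean_expr <- normalize_expression(expr[expr$cell_id %in% cells, ]) |>
    dplyr::summarise(mean_expr = mean(.data$normalized), .by = "gene_id") |>
    dplyr::filter(.data$gene_id %in% gene_models$gene_id)
  gm <- gene_models[gene_models$gene_id %in% mean_expr$gene_id, ]

  # gene-body methylation per gene x group
  obs <- cpg |>
    dplyr::inner_join(assignment[, c("cell_id", "group")], by = "cell_id") |>
    dplyr::mutate(rate = dyad_rate(.data$n_meth, .data$n_unmeth))
  hits <- GenomicRanges::findOverlaps(sites_to_gr(obs$chrom, obs$pos),
                                      intervals_to_gr(gm))
  meth <- obs[S4Vectors::queryHits(hits), ] |>
    dplyr::mutate(gene_id = gm$gene_id[S4Vectors::subjectHits(hits)]) |>
    dplyr::summarise(mean = mean(.data$rate), n = dplyr::n(),
                     .by = c("gene_id", "group")) |>
    dplyr::filter(.data$n >= min_sites)

  # tertiles over genes with any defined methylation
  testable <- mean_expr[mean_expr$gene_id %in% meth$gene_id, ]
  ord <- order(-testable$mean_expr, testable$gene_id)
  sizes <- tertile_sizes(nrow(testable))
  tertiles <- testable[ord, ]
  tertiles$tertile <- factor(rep(c("high", "mid", "low"), times = sizes),
                             levels = c("high", "mid", "low"))
  if (min(sizes) < min_genes) {
    warning("fewer than ", min_genes,
            " genes per tertile after coverage filtering; tests skipped",
            call. = FALSE)
    res <- list(tertiles = tertiles, methylation = meth,
                tests = tibble::tibble(group = character(), pair = character(),
                                       n_a = integer(), n_b = integer(),
                                       p_value = numeric(), q_value = numeric()))
    class(res) <- "tertile_comparison"
    return(res)
  }

  meth <- dplyr::left_join(meth, tertiles[, c("gene_id", "tertile")],
                           by = "gene_id")
  pairs <- list(c("high", "mid"), c("high", "low"), c("mid", "low"))
  tests <- purrr::map_dfr(levels(assignment$group), function(g) {
    purrr::map_dfr(pairs, function(pr) {
      a <- meth$mean[meth$group == g & meth$tertile == pr[1]]
      b <- meth$mean[meth$group == g & meth$tertile == pr[2]]
      if (length(a) < min_genes || length(b) < min_genes) return(NULL)
      p <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                               exact = FALSE)$p.value)
      tibble::tibble(group = g, pair = paste(pr, collapse = "_vs_"),
                     n_a = length(a), n_b = length(b), p_value = p)
    })
  })
  tests$q_value <- stats::p.adjust(tests$p_value, method = "BH")
  res <- list(tertiles = tertiles, methylation = meth, tests = tests)
  class(res) <- "tertile_comparison"
  res
}

#' @export
print.tertile_comparison <- function(x, ...) {
  cat("<tertile_comparison> ", nrow(x$tertiles), " genes, ",
      nrow(x$tests), " Wilcoxon tests (BH-adjusted)\n", sep = "")
  if (nrow(x$tests) > 0) print(x$tests)
  invisible(x)
}

#' Methylated-call fractions and trinucleotide motif breakdown
#'
#' Per methylation group (pooled over member cells): the fraction of
#' methylated calls among CG-context calls and among CH-context calls
#' (CHG and CHH pooled; the finer split is retained), and the
#' distribution of methylated calls over trinucleotide motifs — CH calls
#' over the twelve CAN/CCN/CTN motifs, CG calls over CGA/CGC/CGG/CGT.
#' Call-pooled by default (every sequenced call counts once); site mode
#' counts each covered site once, methylated iff any call is methylated.
#' The spike-in contig and motifs containing ambiguous bases are
#' excluded.
#'
#' @param calls cohort cytosine call tibble (per-strand, all contexts).
#' @param assignment tibble from [assign_groups()].
#' @param lambda_contig spike-in contig.
#' @param mode "call" (pooled calls) or "site" (binarized sites).
#' @return list of class `motif_profile`: `fractions` (group, context
#'   CG/CH/CHG/CHH, n_meth, n_total, fraction), `motifs` (group,
#'   context_class CG/CH, trinucleotide, n_meth, share).
#' @export
noncg_motif_profile <- function(calls, assignment, lambda_contig = "lambda",
                                mode = c("call", "site")) {
  mode <- match.arg(mode)
  if (!"trinucleotide" %in% names(calls) || anyNA(calls$trinucleotide)) {
    abort_param("trinucleotide context required; re-read calls with a reference genome")
  }
  d <- calls |>
    dplyr::filter(.data$chrom != lambda_contig,
                  !grepl("N", .data$trinucleotide, fixed = TRUE)) |>
    dplyr::inner_join(assignment[, c("cell_id", "group")], by = "cell_id")
  if (mode == "site") {
    d <- d |> dplyr::mutate(n_meth = as.integer(.data$n_meth > 0),
                            n_unmeth = as.integer(.data$n_meth == 0))
  }
  d <- d |> dplyr::mutate(
    context_class = ifelse(.data$context == "CG", "CG", "CH"))

  fractions <- dplyr::bind_rows(
    d |> dplyr::summarise(n_meth = sum(.data$n_meth),
                          n_total = sum(.data$n_meth) + sum(.data$n_unmeth),
                          .by = c("group", "context_class")) |>
      dplyr::rename(context = "context_class"),
    d |> dplyr::filter(.data$context_class == "CH") |>
      dplyr::summarise(n_meth = sum(.data$n_meth),
                       n_total = sum(.data$n_meth) + sum(.data$n_unmeth),
                       .by = c("group", "context"))
  ) |>
    dplyr::mutate(fraction = .data$n_meth / .data$n_total) |>
    dplyr::arrange(.data$group, .data$context)

  motifs <- d |>
    dplyr::summarise(n_meth = sum(.data$n_meth),
                     .by = c("group", "context_class", "trinucleotide")) |>
    dplyr::mutate(share = .data$n_meth / sum(.data$n_meth),
                  .by = c("group", "context_class")) |>
    dplyr::arrange(.data$group, .data$context_class, .data$trinucleotide)

  res <- list(fractions = fractions, motifs = motifs)
  class(res) <- "motif_profile"
  res
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("<motif_profile>\n")
  print(x$fractions)
  invisible(x)
}
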