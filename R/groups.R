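# Per-cell global CpG methylation, methylation-level groups (G1..Gk),
# group-wise expression summaries and the mitotic-index split.

#' Global CpG methylation level of a cell
#'
#' Unweighted mean over covered dyads of the per-dyad methylation rate
#' n_meth / (n_meth + n_unmeth) — a site mean, not a pooled-count mean,
#' so deep sites do not dominate. The spike-in contig is excluded.
#'
#' @param cpg strand-merged dyad tibble for one cell.
#' @param lambda_contig spike-in contig name.
#' @return fraction in `[0, 1]`.
#' @export
global_cpg_methylation <- function(cpg, lambda_contig = "lambda") {
  g <- cpg[cpg$chrom != lambda_contig, ]
  if (nrow(g) == 0) abort_param("global methylation undefined: no covered CpG dyads")
  mean(dyad_rate(g$n_meth, g$n_unmeth))
}

#' Global CpG methylation for every cell of a cohort
#' @param cpg merged dyad tibble with a `cell_id` column.
#' @param lambda_contig spike-in contig name.
#' @return tibble: cell_id, level (fraction).
#' @export
cell_methylation_levels <- function(cpg, lambda_contig = "lambda") {
  cpg[cpg$chrom != lambda_contig, ] |>
    dplyr::summarise(level = mean(dyad_rate(.data$n_meth, .data$n_unmeth)),
                     .by = "cell_id")
}

#' Methylation-level grouping schemes
#'
#' Ordered bins of per-cell global CpG methylation (percent) used as a
#' pseudo-developmental ordering. Presets: `"marmoset"` (seven contiguous
#' bins, 0-10 ... 50-60, 60-80), `"human"` (seven bins, 0-20, then decadal
#' to 80), and `"cynomolgus"` (five data-driven, non-contiguous bins).
#' Custom schemes come from a numeric edge vector (contiguous) or a
#' tibble with `label`, `lower`, `upper` columns.
#'
#' @param scheme preset name, numeric edge vector (percent), or tibble.
#' @param labels optional labels when `scheme` is an edge vector
#'   (default G1..Gk).
#' @return tibble of class `meth_scheme`: label, lower, upper (percent).
#' @export
group_scheme <- function(scheme = "marmoset", labels = NULL) {
  if (is.character(scheme) && length(scheme) == 1) {
    tbl <- switch(
      scheme,
      marmoset = scheme_from_edges(c(0, 10, 20, 30, 40, 50, 60, 80)),
      human = scheme_from_edges(c(0, 20, 30, 40, 50, 60, 70, 80)),
      cynomolgus = tibble::tibble(
        label = paste0("G", 1:5),
        lower = c(2.5, 28.4, 52.0, 66.0, 68.2),
        upper = c(4.8, 41.1, 59.5, 67.7, 72.8)
      ),
      abort_param(paste0("unknown scheme preset: ", scheme))
    )
  } else if (is.numeric(scheme)) {
    tbl <- scheme_from_edges(scheme, labels)
  } else if (is.data.frame(scheme)) {
    tbl <- tibble::as_tibble(scheme)
  } else {
    abort_param("scheme must be a preset name, edge vector, or tibble")
  }
  stopifnot(all(c("label", "lower", "upper") %in% names(tbl)),
            all(tbl$lower < tbl$upper))
  if (any(utils::head(tbl$upper, -1) > tbl$lower[-1])) {
    abort_param("scheme bins must be non-overlapping and ascending")
  }
  class(tbl) <- c("meth_scheme", class(tbl))
  tbl
}

scheme_from_edges <- function(edges, labels = NULL) {
  k <- length(edges) - 1
  if (k < 1 || is.unsorted(edges, strictly = TRUE)) {
    abort_param("edges must be a strictly increasing vector")
  }
  tibble::tibble(label = labels %||% paste0("G", seq_len(k)),
                 lower = edges[-length(edges)], upper = edges[-1])
}

#' Assign cells to methylation groups
#'
#' Bins are half-open `[lower, upper)` with the top bin closed at its
#' upper edge, so a level equal to an internal boundary goes to the
#' higher bin. A pure function of the levels and the scheme; input order
#' never matters. Levels outside every bin raise an error naming the
#' cell (possible for non-contiguous data-driven schemes).
#'
#' @param levels tibble (cell_id, level with level a fraction) or a
#'   named numeric vector of fractions.
#' @param scheme `meth_scheme` (bounds in percent).
#' @return tibble: cell_id, level, group (factor ordered by scheme).
#' @export
assign_groups <- function(levels, scheme = group_scheme("marmoset")) {
  if (!is.data.frame(levels)) {
    levels <- tibble::tibble(cell_id = names(levels), level = unname(levels))
  }
  pct <- levels$level * 100
  top <- nrow(scheme)
  idx <- vapply(pct, function(x) {
    hit <- which(x >= scheme$lower &
                   (x < scheme$upper | (seq_len(top) == top & x == scheme$upper)))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    abort_param(sprintf("cell %s has level %.3g%% outside the scheme range",
                        levels$cell_id[bad], pct[bad]))
  }
  tibble::tibble(cell_id = levels$cell_id, level = levels$level,
                 group = factor(scheme$label[idx], levels = scheme$label))
}

#' Per-group cell counts
#' @param assignment tibble from [assign_groups()].
#' @return tibble: group, n.
#' @export
group_counts <- function(assignment) {
  assignment |>
    dplyr::count(.data$group, .drop = FALSE, name = "n")
}

#' Log library-size normalization of expression counts
#'
#' `log1p(count / library_size * 1e4)` per cell — the standard log-scaled
#' library-size normalization for single-cell counts.
#'
#' @param expr long tibble (gene_id, cell_id, count).
#' @return same tibble with a `normalized` column.
#' @export
normalize_expression <- function(expr) {
  expr |>
    dplyr::mutate(lib = sum(.data$count), .by = "cell_id") |>
    dplyr::mutate(normalized = log1p(.data$count / .data$lib * 1e4)) |>
    dplyr::select(-"lib")
}

#' Mean normalized expression per methylation group
#'
#' @param expr long expression tibble (gene_id, cell_id, count).
#' @param assignment tibble from [assign_groups()].
#' @param genes gene ids to report; genes absent from the matrix are
#'   returned with NA means and listed in the `missing` attribute, never
#'   silently zero-filled.
#' @return tibble: gene_id, group, mean_normalized.
#' @export
summarize_expression_by_group <- function(expr, assignment, genes = NULL) {
  genes <- genes %||% unique(expr$gene_id)
  absent <- setdiff(genes, unique(expr$gene_id))
  if (length(absent) > 0) {
    warning("gene(s) absent from expression matrix: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  # normalize against the full per-cell library before selecting genes
  keep <- normalize_expression(expr[expr$cell_id %in% assignment$cell_id, ])
  keep <- keep[keep$gene_id %in% genes, ]
  means <- keep |>
    dplyr::inner_join(assignment[, c("cell_id", "group")], by = "cell_id") |>
    dplyr::summarise(mean_normalized = mean(.data$normalized),
                     .by = c("gene_id", "group"))
  grid <- tidyr::expand_grid(
    gene_id = genes,
    group = factor(levels(assignment$group), levels = levels(assignment$group)))
  out <- dplyr::left_join(grid, means, by = c("gene_id", "group"))
  attr(out, "missing") <- absent
  out
}

#' Mitotic-index calls from cell-cycle gene expression
#'
#' Score = mean normalized expression of the S/G2/M gene set minus the
#' mean of a size-matched random control gene set (fixed seed); cells
#' with a positive score are called S/G2/M, the rest G0.
#'
#' @param expr long expression tibble.
#' @param cycle_genes S/G2/M gene ids (>= 1 present in the matrix).
#' @param control_size control set size (default: size-matched).
#' @param seed seed for the control draw.
#' @return tibble: cell_id, mitotic_score, phase ("G0" or "S/G2/M").
#' @export
mitotic_index <- function(expr, cycle_genes, control_size = NULL, seed = 1) {
  present <- intersect(cycle_genes, unique(expr$gene_id))
  if (length(present) == 0) abort_param("no cycle gene present in the expression matrix")
  pool <- setdiff(unique(expr$gene_id), cycle_genes)
  control_size <- control_size %||% length(present)
  if (length(pool) == 0) abort_param("no genes left for the control set")
  set.seed(seed)
  control <- sample(pool, min(control_size, length(pool)))
  norm <- normalize_expression(expr)
  score <- norm |>
    dplyr::summarise(
      mitotic_score = mean(.data$normalized[.data$gene_id %in% present]) -
        mean(.data$normalized[.data$gene_id %in% control]),
      .by = "cell_id")
  score$phase <- ifelse(score$mitotic_score > 0, "S/G2/M", "G0")
  score
}
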