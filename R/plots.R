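# ggplot2 views of the result tables.

#' Per-cell global methylation by stage and group
#'
#' One point per cell (the scBS-seq global CpG level), colored by
#' methylation group — the standard establishment-trajectory view.
#'
#' @param assignment tibble from [assign_groups()].
#' @param sheet optional sample sheet providing a `stage` column.
#' @return a ggplot.
#' @export
plot_cell_levels <- function(assignment, sheet = NULL) {
  d <- assignment
  if (!is.null(sheet) && "stage" %in% names(sheet)) {
    d <- dplyr::left_join(d, sheet[, c("cell_id", "stage")], by = "cell_id")
    d$stage <- factor(d$stage, levels = unique(sheet$stage))
  } else {
    d$stage <- ""
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stage, y = 100 * .data$level,
                                  color = .data$group)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.6) +
    ggplot2::labs(x = "stage", y = "global CpG methylation (%)",
                  color = "group") +
    ggplot2::theme_minimal()
}

#' Tile methylation tracks by group
#'
#' Group-mean methylation along a chromosome, one line per group —
#' the tiled establishment track.
#'
#' @param tm `tile_means` tibble.
#' @param chrom chromosome to draw (default: first).
#' @return a ggplot.
#' @export
plot_tile_tracks <- function(tm, chrom = NULL) {
  chrom <- chrom %||% tm$chrom[1]
  d <- tm[tm$chrom == chrom & !is.na(tm$mean), ]
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                  y = .data$mean, color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste0(chrom, " (Mb)"), y = "mean CpG methylation",
                  color = "group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tile_kinetics <- function(object, ...) {
  d <- object[object$class != "unclassified", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$score,
                                  color = .data$class)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = "kinetic class", y = "kinetic score S") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Context methylation profile heat/line view
#'
#' @param profile tibble from [context_methylation_profile()].
#' @return a ggplot.
#' @export
plot_context_profile <- function(profile) {
  ggplot2::ggplot(profile[!is.na(profile$mean), ],
                  ggplot2::aes(x = .data$group, y = .data$mean,
                               group = .data$category,
                               color = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "methylation group", y = "mean CpG methylation",
                  color = "context") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Motif shares of methylated non-CpG calls
#'
#' @param mp `motif_profile`.
#' @param context_class "CH" or "CG".
#' @return a ggplot.
#' @export
plot_motif_profile <- function(mp, context_class = "CH") {
  d <- mp$motifs[mp$motifs$context_class == context_class, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$share,
                                  fill = .data$trinucleotide)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "methylation group",
                  y = "share of methylated calls", fill = "motif") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
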