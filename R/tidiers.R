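# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname tidiers
#' @param x a `tile_kinetics` tibble.
#' @param ... unused.
tidy.tile_kinetics <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidiers for kinetic classifications and tertile comparisons
#'
#' `tidy()` returns the per-unit table (tiles or tests); `glance()` a
#' one-row summary.
#'
#' @name tidiers
NULL

#' @export
#' @rdname tidiers
glance.tile_kinetics <- function(x, ...) {
  cl <- if ("class" %in% names(x)) x$class else rep(NA_character_, nrow(x))
  tibble::tibble(
    n_tiles = nrow(x),
    n_scored = sum(!is.na(x$score)),
    n_fast = sum(cl == "fast", na.rm = TRUE),
    n_intermediate = sum(cl == "intermediate", na.rm = TRUE),
    n_slow = sum(cl == "slow", na.rm = TRUE),
    median_score = stats::median(x$score, na.rm = TRUE)
  )
}

#' @export
#' @rdname tidiers
tidy.tertile_comparison <- function(x, ...) tibble::as_tibble(x$tests)

#' @export
#' @rdname tidiers
glance.tertile_comparison <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$tertiles),
    n_tests = nrow(x$tests),
    n_significant = sum(x$tests$q_value < 0.05)
  )
}

#' @export
#' @rdname tidiers
tidy.motif_profile <- function(x, ...) tibble::as_tibble(x$motifs)

#' @export
#' @rdname tidiers
glance.motif_profile <- function(x, ...) {
  ch <- x$fractions[x$fractions$context == "CH", ]
  tibble::tibble(
    n_groups = dplyr::n_distinct(x$fractions$group),
    ch_fraction_min = min(ch$fraction),
    ch_fraction_max = max(ch$fraction)
  )
}
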