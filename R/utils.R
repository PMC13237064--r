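# Internal helpers shared across modules.
#
# Coordinate convention: interval tables (annotations, tiles, gene models)
# are 0-based half-open [start, end), as in BED. Per-cytosine tables carry
# the 1-based position of the C on its own strand, as in Bismark cytosine
# reports. Conversion happens only where sites meet intervals.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_param <- function(msg) stop(msg, call. = FALSE)

check_interval_tbl <- function(tbl, what = "interval table") {
  needed <- c("chrom", "start", "end")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort_param(sprintf("%s lacks column(s): %s", what,
                        paste(missing, collapse = ", ")))
  }
  bad <- which(tbl$start >= tbl$end)
  if (length(bad) > 0) {
    abort_param(sprintf("%s has start >= end at row %d", what, bad[1]))
  }
  invisible(tbl)
}

intervals_to_gr <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges   = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

# 1-based point positions -> GRanges of width 1
sites_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = pos, width = 1L))
}

# logical: does each site (1-based pos) fall inside any interval of `tbl`?
sites_in_intervals <- function(chrom, pos, tbl) {
  if (nrow(tbl) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  IRanges::overlapsAny(sites_to_gr(chrom, pos), intervals_to_gr(tbl))
}

# merged (union) footprint of an interval table, as a tibble
union_intervals <- function(tbl) {
  if (nrow(tbl) == 0) return(tbl[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_gr(tbl))
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

# total bp of overlap between two interval tables (union footprints)
overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  hit <- GenomicRanges::intersect(
    GenomicRanges::reduce(intervals_to_gr(a)),
    GenomicRanges::reduce(intervals_to_gr(b))
  )
  sum(GenomicRanges::width(hit))
}

# sizes of an ascending three-way split of n items; remainder goes to the
# earlier bins so the split is deterministic and reproducible by a planter
tertile_sizes <- function(n) {
  k <- n %/% 3L
  r <- n %% 3L
  c(k + as.integer(r > 0), k + as.integer(r > 1), k)
}

# per-dyad methylation rate
dyad_rate <- function(n_meth, n_unmeth) n_meth / (n_meth + n_unmeth)

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

context_of_trinuc <- function(trinuc) {
  second <- substr(trinuc, 2, 2)
  third <- substr(trinuc, 3, 3)
  dplyr::case_when(
    second == "G" ~ "CG",
    third == "G" ~ "CHG",
    TRUE ~ "CHH"
  )
}
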