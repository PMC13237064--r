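# On-disk formats: Bismark-style cytosine reports (two dialects), BED6
# annotations, sample sheets, expression tables.
#
# Cytosine reports are 1-based per-strand positions; BED is 0-based
# half-open. All interval computation in the package is 0-based
# half-open; conversion happens in this file only.

report_cols <- c("chrom", "pos", "strand", "n_meth", "n_unmeth",
                 "context", "trinucleotide")

#' Read a per-cell cytosine call file
#'
#' Supports two tab-separated dialects. `cytosine_report` is the
#' Coverage2cytosine layout: chrom, 1-based position, strand, methylated
#' count, unmethylated count, context (CG/CHG/CHH), trinucleotide.
#' `coverage` is the bedGraph-derived coverage layout: chrom, start, end
#' (both 1-based, start == end for a single cytosine), methylation
#' percentage, methylated count, unmethylated count; it carries no strand
#' or context, so a reference sequence must be supplied to recover them
#' (the base at the position decides the strand: C is +, G is -).
#'
#' Zero-coverage rows (present in full cytosine reports) are dropped.
#'
#' @param path file path.
#' @param dialect "cytosine_report" or "coverage"; never sniffed.
#' @param genome named character vector of contig sequences, a
#'   `sim_genome`, or a FASTA path; required for the coverage dialect.
#' @param cell_id cell identifier attached to every row; defaults to the
#'   file name without extensions.
#' @return tibble of calls: cell_id, chrom, pos, strand, context,
#'   trinucleotide, n_meth, n_unmeth.
#' @export
read_cytosine_report <- function(path, dialect = c("cytosine_report", "coverage"),
                                 genome = NULL, cell_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_param(paste0("no such file: ", path))
  cell_id <- cell_id %||% sub("\\..*$", "", basename(path))
  empty <- tibble::tibble(cell_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          context = character(), trinucleotide = character(),
                          n_meth = integer(), n_unmeth = integer())
  if (file.size(path) == 0) {
    warning("empty call file: ", path, call. = FALSE)
    return(empty)
  }
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  n_expect <- if (dialect == "cytosine_report") 7L else 6L
  if (ncol(raw) != n_expect) {
    abort_param(sprintf("%s: expected %d tab-separated columns, found %d",
                        path, n_expect, ncol(raw)))
  }
  if (dialect == "cytosine_report") {
    tbl <- tibble::tibble(
      cell_id = cell_id, chrom = raw[[1]],
      pos = suppressWarnings(as.integer(raw[[2]])), strand = raw[[3]],
      context = raw[[6]], trinucleotide = raw[[7]],
      n_meth = suppressWarnings(as.integer(raw[[4]])),
      n_unmeth = suppressWarnings(as.integer(raw[[5]]))
    )
    bad <- which(is.na(tbl$pos) | is.na(tbl$n_meth) | is.na(tbl$n_unmeth) |
                   !tbl$strand %in% c("+", "-"))
  } else {
    if (is.null(genome)) {
      abort_param("coverage dialect carries no strand/context; supply `genome`")
    }
    seqs <- load_sequences(genome)
    tbl <- tibble::tibble(
      cell_id = cell_id, chrom = raw[[1]],
      pos = suppressWarnings(as.integer(raw[[2]])),
      n_meth = suppressWarnings(as.integer(raw[[5]])),
      n_unmeth = suppressWarnings(as.integer(raw[[6]]))
    )
    bad <- which(is.na(tbl$pos) | is.na(tbl$n_meth) | is.na(tbl$n_unmeth))
    if (length(bad) == 0) {
      ctx <- context_from_sequence(seqs, tbl$chrom, tbl$pos)
      tbl$strand <- ctx$strand
      tbl$context <- ctx$context
      tbl$trinucleotide <- ctx$trinucleotide
      tbl <- tbl[, c("cell_id", "chrom", "pos", "strand", "context",
                     "trinucleotide", "n_meth", "n_unmeth")]
    }
  }
  if (length(bad) > 0) {
    abort_param(sprintf("%s: malformed row at line %d", path, bad[1]))
  }
  tbl <- tbl[tbl$n_meth + tbl$n_unmeth >= 1L, ]
  if (nrow(tbl) == 0) warning("no covered cytosines in ", path, call. = FALSE)
  tbl
}

load_sequences <- function(genome) {
  if (inherits(genome, "sim_genome")) return(unlist(genome$sequence))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  abort_param("genome must be a sim_genome, named sequences, or a FASTA path")
}

context_from_sequence <- function(seqs, chrom, pos) {
  strand <- character(length(pos))
  trinuc <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- seqs[[ch]]
    if (is.null(s) || is.na(s)) abort_param(paste0("contig absent from reference: ", ch))
    padded <- paste0("NN", s, "NN")
    base <- substring(s, pos[idx], pos[idx])
    if (any(!base %in% c("C", "G"))) {
      abort_param(sprintf("position %d on %s is not a cytosine on either strand",
                          pos[idx][which(!base %in% c("C", "G"))[1]], ch))
    }
    plus <- base == "C"
    strand[idx] <- ifelse(plus, "+", "-")
    tri <- ifelse(plus,
                  substring(padded, pos[idx] + 2L, pos[idx] + 4L),
                  NA_character_)
    if (any(!plus)) {
      tri[!plus] <- reverse_complement(
        substring(padded, pos[idx][!plus], pos[idx][!plus] + 2L))
    }
    trinuc[idx] <- tri
  }
  list(strand = strand, context = context_of_trinuc(trinuc),
       trinucleotide = trinuc)
}

#' Write a cytosine report (cytosine_report dialect)
#' @param calls call tibble (as returned by [read_cytosine_report()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(calls, path) {
  out <- calls[, report_cols]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Merge CpG calls across strands into dyads
#'
#' The two cytosines of a CpG dyad report the same methylation state; the
#' merged table is keyed by the 1-based position of the + strand C and
#' sums counts over whichever strands were observed (dyads covered on one
#' strand only are kept with that strand's counts). Total counts are
#' conserved: the merged counts sum to the unmerged CG counts.
#'
#' @param calls call tibble; only `context == "CG"` rows are used.
#' @return tibble: cell_id, chrom, pos (dyad key), n_meth, n_unmeth.
#' @export
merge_cpg_strands <- function(calls) {
  cg <- calls[calls$context == "CG", ]
  if (nrow(cg) == 0) {
    return(tibble::tibble(cell_id = character(), chrom = character(),
                          pos = integer(), n_meth = integer(),
                          n_unmeth = integer()))
  }
  cg |>
    dplyr::mutate(pos = ifelse(.data$strand == "-", .data$pos - 1L, .data$pos)) |>
    dplyr::summarise(n_meth = sum(.data$n_meth), n_unmeth = sum(.data$n_unmeth),
                     .by = c("cell_id", "chrom", "pos")) |>
    dplyr::arrange(.data$cell_id, .data$chrom, .data$pos)
}

#' Read BED6 annotation files into one interval table
#'
#' @param paths named character vector, category -> BED path (BED6,
#'   0-based half-open; name and score columns optional).
#' @param chrom_sizes named contig lengths; needed to derive the
#'   complement categories.
#' @param flank_size bp used when deriving "flanking"/"intergenic".
#' @param derive derive "flanking" and "intergenic" from the "gene"
#'   category when they are not provided.
#' @return tibble: category, chrom, start, end, name, score.
#' @export
read_bed_annotations <- function(paths, chrom_sizes = NULL, flank_size = 2000,
                                 derive = TRUE) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort_param("paths must be a named vector: category -> BED file")
  }
  ann <- purrr::imap_dfr(paths, function(p, category) {
    raw <- readr::read_tsv(p, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(raw) < 3) abort_param(paste0(p, ": BED needs >= 3 columns"))
    tbl <- tibble::tibble(
      category = category, chrom = as.character(raw[[1]]),
      start = as.integer(raw[[2]]), end = as.integer(raw[[3]]),
      name = if (ncol(raw) >= 4) as.character(raw[[4]]) else NA_character_,
      score = if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else 0
    )
    check_interval_tbl(tbl, paste0("BED file ", p))
  })
  if (derive && !is.null(chrom_sizes) && "gene" %in% ann$category) {
    genes <- ann[ann$category == "gene", ]
    if (!"flanking" %in% ann$category) {
      ann <- dplyr::bind_rows(ann, derive_flanking(genes, chrom_sizes, flank_size))
    }
    if (!"intergenic" %in% ann$category) {
      ann <- dplyr::bind_rows(ann, derive_intergenic(genes, chrom_sizes, flank_size))
    }
  }
  ann
}

#' Read / write a sample sheet
#'
#' Tab-separated with header: cell_id, stage, age, mapping_rate,
#' call_file. Cell ids must be unique and mapping rates in `[0, 1]`.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("cell_id", "mapping_rate")
  miss <- setdiff(needed, names(sheet))
  if (length(miss) > 0) {
    abort_param(paste0("sample sheet lacks column(s): ", paste(miss, collapse = ", ")))
  }
  validate_sample_sheet(sheet)
}

validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$cell_id)) {
    abort_param(paste0("duplicate cell_id in sample sheet: ",
                       sheet$cell_id[duplicated(sheet$cell_id)][1]))
  }
  if (any(sheet$mapping_rate < 0 | sheet$mapping_rate > 1, na.rm = TRUE)) {
    abort_param("mapping_rate must lie in [0, 1]")
  }
  tibble::as_tibble(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet tibble.
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_tsv(validate_sample_sheet(sheet), path, progress = FALSE)
  invisible(path)
}

#' Read / write an expression matrix
#'
#' On disk: genes x cells TSV with a `gene_id` first column. In memory:
#' long tibble (gene_id, cell_id, count).
#'
#' @param path TSV path.
#' @return long tibble.
#' @export
read_expression <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tidyr::pivot_longer(wide, -"gene_id", names_to = "cell_id",
                      values_to = "count")
}

#' @rdname read_expression
#' @param expr long expression tibble.
#' @export
write_expression <- function(expr, path) {
  wide <- tidyr::pivot_wider(expr, names_from = "cell_id",
                             values_from = "count", values_fill = 0)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
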