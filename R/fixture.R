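#' Write a synthetic cohort to disk as a complete fixture
#'
#' Emits everything a pipeline run needs: the genome FASTA, one BED per
#' annotation category, one cytosine-report call file per cell, the
#' sample sheet (call_file column filled), the expression matrix, and
#' the planted truth tables (tile classes and cell labels). A manifest
#' listing every file with its MD5 checksum is written last, so a
#' re-emitted cohort can be verified byte-for-byte.
#'
#' @param cohort `sim_cohort`.
#' @param out_dir output directory (created if needed).
#' @return tibble manifest (file, md5), invisibly written to
#'   `manifest.tsv`.
#' @export
emit_fixture <- function(cohort, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to ", out_dir, call. = FALSE)
  }
  dir.create(file.path(out_dir, "cells"), showWarnings = FALSE)

  files <- character(0)
  fa <- file.path(out_dir, "genome.fa")
  write_genome_fasta(cohort$genome, fa)
  files <- c(files, fa)
  files <- c(files, write_annotation_beds(cohort$genome, file.path(out_dir, "beds")))

  sheet <- cohort$sheet
  for (i in seq_len(nrow(sheet))) {
    p <- file.path(out_dir, "cells", paste0(sheet$cell_id[i], ".CX_report.txt"))
    write_cytosine_report(cohort$calls[cohort$calls$cell_id == sheet$cell_id[i], ], p)
    sheet$call_file[i] <- file.path("cells", basename(p))
    files <- c(files, p)
  }
  ss <- file.path(out_dir, "sample_sheet.tsv")
  write_sample_sheet(sheet, ss)
  ex <- file.path(out_dir, "expression.tsv")
  write_expression(cohort$expression, ex)
  tt <- file.path(out_dir, "truth_tiles.tsv")
  readr::write_tsv(cohort$genome$tiles, tt, progress = FALSE)
  tc <- file.path(out_dir, "truth_cells.tsv")
  readr::write_tsv(cohort$cell_truth, tc, progress = FALSE)
  files <- c(files, ss, ex, tt, tc)

  rel <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
             normalizePath(files))
  manifest <- tibble::tibble(file = rel,
                             md5 = unname(tools::md5sum(files)))
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"), progress = FALSE)
  invisible(manifest)
}

#' Validate an emitted fixture against its manifest
#'
#' @param dir fixture directory containing `manifest.tsv`.
#' @return TRUE invisibly if every listed file exists with a matching
#'   checksum; otherwise an error naming the first offending file.
#' @export
validate_manifest <- function(dir) {
  mp <- file.path(dir, "manifest.tsv")
  if (!file.exists(mp)) abort_param(paste0("no manifest.tsv under ", dir))
  manifest <- readr::read_tsv(mp, show_col_types = FALSE, progress = FALSE)
  paths <- file.path(dir, manifest$file)
  gone <- !file.exists(paths)
  if (any(gone)) {
    abort_param(paste0("manifest validation failed: missing file ",
                       manifest$file[which(gone)[1]]))
  }
  md5 <- unname(tools::md5sum(paths))
  diff <- md5 != manifest$md5
  if (any(diff)) {
    abort_param(paste0("manifest validation failed: checksum mismatch for ",
                       manifest$file[which(diff)[1]]))
  }
  invisible(TRUE)
}
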