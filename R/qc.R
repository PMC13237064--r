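# Per-cell quality control: conversion rate from the unmethylated lambda
# spike-in, CpG dyad coverage rate, somatic-contamination flag from
# maternally methylated imprinted DMRs, and the exclusion decision.

#' Bisulfite conversion rate from the lambda spike-in
#'
#' The spike-in is fully unmethylated, so every methylated call on it is
#' a conversion failure; the rate is the pooled unmethylated fraction
#' over all lambda cytosines, all contexts.
#'
#' @param calls per-cell call tibble (one cell).
#' @param lambda_contig spike-in contig name.
#' @return fraction in `[0, 1]`.
#' @export
estimate_conversion_rate <- function(calls, lambda_contig = "lambda") {
  lam <- calls[calls$chrom == lambda_contig, ]
  tot <- sum(lam$n_meth) + sum(lam$n_unmeth)
  if (nrow(lam) == 0 || tot == 0) {
    abort_param("conversion rate undefined: no covered cytosines on the spike-in contig")
  }
  sum(lam$n_unmeth) / tot
}

#' CpG dyad coverage rate
#'
#' Fraction of reference CpG dyads (spike-in excluded) covered by at
#' least one call in the cell.
#'
#' @param cpg strand-merged dyad tibble for one cell.
#' @param genome_cpg_count total dyads in the reference, spike-in
#'   excluded (see [count_cpg_dyads()]).
#' @param lambda_contig spike-in contig name.
#' @return fraction in `[0, 1]`.
#' @export
compute_coverage_rate <- function(cpg, genome_cpg_count, lambda_contig = "lambda") {
  if (genome_cpg_count <= 0) abort_param("genome_cpg_count must be positive")
  nrow(cpg[cpg$chrom != lambda_contig, ]) / genome_cpg_count
}

#' Flag somatic-cell contamination at maternally methylated imprinted DMRs
#'
#' Maternally methylated imprinted DMRs are ~50% methylated in somatic
#' cells but unmethylated in the male germline. A cell is flagged when
#' the mean (across DMRs with at least `min_sites` covered dyads) of
#' per-DMR mean methylation reaches `threshold`. With no sufficiently
#' covered DMR the status is indeterminate: the flag is NA with a
#' warning, never silently FALSE.
#'
#' @param cpg strand-merged dyad tibble for one cell.
#' @param dmrs interval tibble of imprinted DMRs (chrom/start/end/name).
#' @param threshold mean-methylation cutoff (default 0.25, separating
#'   ~0.5 somatic from ~0 germline with margin).
#' @param min_sites minimum covered dyads for a DMR to qualify.
#' @return list: `somatic_flag` (logical or NA), `imprint_means` (tibble
#'   name/mean/n_sites per DMR).
#' @export
flag_somatic_by_imprints <- function(cpg, dmrs, threshold = 0.25, min_sites = 5) {
  check_interval_tbl(dmrs, "imprinted DMR table")
  inside <- sites_in_intervals(cpg$chrom, cpg$pos, dmrs)
  hits <- cpg[inside, ]
  per_dmr <- purrr::pmap_dfr(dmrs, function(chrom, start, end, ...) {
    sel <- hits$chrom == chrom & hits$pos > start & hits$pos <= end
    tibble::tibble(
      name = list(...)$name %||% sprintf("%s:%d-%d", chrom, start, end),
      mean = if (any(sel)) mean(dyad_rate(hits$n_meth[sel], hits$n_unmeth[sel])) else NA_real_,
      n_sites = sum(sel)
    )
  })
  ok <- per_dmr$n_sites >= min_sites
  if (!any(ok)) {
    warning("somatic status indeterminate: no imprinted DMR with >= ",
            min_sites, " covered sites", call. = FALSE)
    return(list(somatic_flag = NA, imprint_means = per_dmr))
  }
  list(somatic_flag = mean(per_dmr$mean[ok]) >= threshold,
       imprint_means = per_dmr)
}

#' Per-cell QC table for a cohort
#'
#' Computes conversion rate, coverage rate and the somatic flag for every
#' cell and joins the sample sheet's mapping rate.
#'
#' @param calls cohort call tibble (all cells).
#' @param sheet sample sheet.
#' @param dmrs imprinted DMR interval tibble.
#' @param genome_cpg_count reference dyad count (spike-in excluded).
#' @param lambda_contig spike-in contig name.
#' @param threshold,min_sites see [flag_somatic_by_imprints()].
#' @param cpg optional precomputed merged dyad tibble.
#' @return tibble: cell_id, conversion_rate, coverage_rate, mapping_rate,
#'   imprint_mean, somatic_flag.
#' @export
qc_cells <- function(calls, sheet, dmrs, genome_cpg_count,
                     lambda_contig = "lambda", threshold = 0.25,
                     min_sites = 5, cpg = NULL) {
  cpg <- cpg %||% merge_cpg_strands(calls)
  purrr::map_dfr(sheet$cell_id, function(cid) {
    cc <- calls[calls$cell_id == cid, ]
    cg <- cpg[cpg$cell_id == cid, ]
    conv <- tryCatch(estimate_conversion_rate(cc, lambda_contig),
                     error = function(e) NA_real_)
    som <- flag_somatic_by_imprints(cg, dmrs, threshold, min_sites)
    qualifying <- som$imprint_means$n_sites >= min_sites
    tibble::tibble(
      cell_id = cid,
      conversion_rate = conv,
      coverage_rate = compute_coverage_rate(cg, genome_cpg_count, lambda_contig),
      mapping_rate = sheet$mapping_rate[match(cid, sheet$cell_id)],
      imprint_mean = if (any(qualifying)) mean(som$imprint_means$mean[qualifying]) else NA_real_,
      somatic_flag = som$somatic_flag
    )
  })
}

#' Apply the cell exclusion criteria
#'
#' Two criteria: coverage rate below `coverage_min` (default 1% of
#' reference CpG dyads), and the somatic-contamination flag. Mapping
#' rate is reported but acts only through its coverage consequence; a
#' conversion-rate floor is off by default. A cell failing several
#' criteria is excluded once, with every reason recorded.
#'
#' @param sheet sample sheet.
#' @param qc tibble from [qc_cells()], one row per sheet row.
#' @param coverage_min exclusion threshold on coverage rate.
#' @param conversion_min optional floor on conversion rate (NULL = off).
#' @return the sheet joined with QC, plus `included` (logical) and
#'   `reasons` (";"-separated, empty iff included).
#' @export
apply_exclusions <- function(sheet, qc, coverage_min = 0.01,
                             conversion_min = NULL) {
  if (anyDuplicated(sheet$cell_id)) {
    abort_param("duplicate cell_id in sample sheet")
  }
  if (!setequal(sheet$cell_id, qc$cell_id)) {
    abort_param("QC table must carry exactly one record per sheet row")
  }
  out <- dplyr::left_join(tibble::as_tibble(sheet), qc,
                          by = "cell_id",
                          suffix = c("", ".qc"))
  reasons <- purrr::pmap_chr(out, function(coverage_rate, somatic_flag,
                                           conversion_rate, ...) {
    r <- character(0)
    if (coverage_rate < coverage_min) {
      r <- c(r, sprintf("coverage_rate<%g", coverage_min))
    }
    if (isTRUE(somatic_flag)) r <- c(r, "somatic_contamination")
    if (!is.null(conversion_min) && !is.na(conversion_rate) &&
          conversion_rate < conversion_min) {
      r <- c(r, sprintf("conversion_rate<%g", conversion_min))
    }
    paste(r, collapse = ";")
  })
  out$reasons <- reasons
  out$included <- reasons == ""
  out
}
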