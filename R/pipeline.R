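# End-to-end driver: runs the analysis stages over an on-disk fixture
# (simulated here or provided), writing one TSV per result.

#' Run the analysis pipeline over a configuration
#'
#' Stages: `simulate` (build the synthetic genome and cohort, emit the
#' fixture), `qc` (per-cell QC and exclusions -> `qc_cells.tsv`),
#' `group` (`cell_levels.tsv`, `group_counts.tsv`, `expr_by_group.tsv`,
#' `cycle_calls.tsv`), `kinetics` (`tile_means.tsv`,
#' `tile_kinetics.bed`, `enrichment.tsv`, `gene_kinetics.tsv`),
#' `contexts` (`context_profile.tsv`, `masked_means.tsv`,
#' `tertile_tests.tsv`), `noncg` (`motif_profile.tsv`), or `all`.
#' Parameters, seed and package version are logged to
#' `<out_dir>/pipeline_log.txt` and to stderr.
#'
#' @param config path to a YAML file or an equivalent named list. Keys:
#'   `out_dir` (required), `seed`, `scheme` (preset name or numeric edge
#'   vector), `tile_size`, `min_sites`, `coverage_min`, `flank_size`,
#'   `species` (chooses scoring pairs), `simulate` (arguments for
#'   [genome_config()] / [kinetic_model()] / [simulate_cells()], as
#'   sublists `genome`, `model`, `cells`), and `fixture_dir` (an already
#'   emitted fixture, when the simulate stage is not run).
#' @param stages character vector of stage names, or "all".
#' @return invisible named list of written output paths.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config)) {
    if (!file.exists(config)) abort_param(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_param("config must be a YAML path or a list")
  known <- c("simulate", "qc", "group", "kinetics", "contexts", "noncg")
  if (identical(stages, "all")) stages <- known
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    abort_param(paste0("unknown stage(s): ", paste(bad, collapse = ", "),
                       "; known: ", paste(c(known, "all"), collapse = ", ")))
  }
  out_dir <- config$out_dir %||% abort_param("config needs out_dir")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed %||% 1L
  log_path <- file.path(out_dir, "pipeline_log.txt")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  logf("scmethkin %s | seed=%s | stages=%s",
       as.character(utils::packageVersion("scmethkin")), seed,
       paste(stages, collapse = ","))

  fixture_dir <- config$fixture_dir %||% file.path(out_dir, "fixture")
  outputs <- list()

  if ("simulate" %in% stages) {
    sim <- config$simulate %||% list()
    gcfg <- do.call(genome_config, c(sim$genome %||% list(), list(seed = seed)))
    model <- do.call(kinetic_model, c(sim$model %||% list(), list(seed = seed)))
    genome <- build_genome(gcfg)
    cohort <- do.call(simulate_cells,
                      c(list(genome = genome, model = model), sim$cells %||% list()))
    emit_fixture(cohort, fixture_dir)
    logf("simulate: %d cells -> %s", nrow(cohort$sheet), fixture_dir)
  }

  fx <- load_fixture(fixture_dir, flank_size = config$flank_size %||% 2000)
  lambda <- config$lambda_contig %||% "lambda"
  scheme <- group_scheme(config$scheme %||% "marmoset")
  pairs <- scoring_pairs(config$species %||% "marmoset")

  qc <- qc_cells(fx$calls, fx$sheet, fx$annotations |>
                   dplyr::filter(.data$category == "imprint_dmr"),
                 genome_cpg_count = fx$genome_cpg_count,
                 lambda_contig = lambda, cpg = fx$cpg)
  filtered <- apply_exclusions(fx$sheet, qc,
                               coverage_min = config$coverage_min %||% 0.01)
  if ("qc" %in% stages) {
    outputs$qc <- file.path(out_dir, "qc_cells.tsv")
    readr::write_tsv(filtered, outputs$qc, progress = FALSE)
    logf("qc: %d/%d cells retained", sum(filtered$included), nrow(filtered))
  }

  keep <- filtered$cell_id[filtered$included]
  cpg <- fx$cpg[fx$cpg$cell_id %in% keep, ]
  levels <- cell_methylation_levels(cpg, lambda)
  assignment <- assign_groups(levels, scheme)

  if ("group" %in% stages) {
    outputs$cell_levels <- file.path(out_dir, "cell_levels.tsv")
    readr::write_tsv(assignment, outputs$cell_levels, progress = FALSE)
    outputs$group_counts <- file.path(out_dir, "group_counts.tsv")
    readr::write_tsv(group_counts(assignment), outputs$group_counts, progress = FALSE)
    if (!is.null(fx$expression)) {
      expr <- fx$expression[fx$expression$cell_id %in% keep, ]
      outputs$expr_by_group <- file.path(out_dir, "expr_by_group.tsv")
      readr::write_tsv(summarize_expression_by_group(expr, assignment),
                       outputs$expr_by_group, progress = FALSE)
      cyc <- intersect(sim_cycle_genes(), unique(expr$gene_id))
      if (length(cyc) > 0) {
        outputs$cycle_calls <- file.path(out_dir, "cycle_calls.tsv")
        readr::write_tsv(mitotic_index(expr, cyc, seed = seed),
                         outputs$cycle_calls, progress = FALSE)
      }
    }
    logf("group: %d cells across %d bins", nrow(assignment), nrow(scheme))
  }

  if ("kinetics" %in% stages) {
    tm <- tile_group_means(cpg, assignment, fx$chrom_sizes,
                           tile_size = config$tile_size %||% 5e5,
                           min_sites = config$min_sites %||% 50)
    tk <- kinetic_score(tm, pairs$early, pairs$late) |> classify_kinetics()
    outputs$tile_means <- file.path(out_dir, "tile_means.tsv")
    readr::write_tsv(tm, outputs$tile_means, progress = FALSE)
    outputs$tile_bed <- file.path(out_dir, "tile_kinetics.bed")
    readr::write_tsv(tk |>
                       dplyr::transmute(.data$chrom, .data$start, .data$end,
                                        name = .data$class,
                                        score = round(.data$score * 1000),
                                        strand = "."),
                     outputs$tile_bed, col_names = FALSE, progress = FALSE)
    enr <- annotation_enrichment(tk, fx$annotations |>
                                   dplyr::filter(!.data$category %in%
                                                   c("imprint_dmr")))
    outputs$enrichment <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(enr, outputs$enrichment, progress = FALSE)
    if (!is.null(fx$gene_models)) {
      gk <- gene_body_kinetics(cpg, assignment, fx$gene_models,
                               fx$annotations |>
                                 dplyr::filter(.data$category == "atac_peak"),
                               pairs$early, pairs$late)
      outputs$gene_kinetics <- file.path(out_dir, "gene_kinetics.tsv")
      readr::write_tsv(gk, outputs$gene_kinetics, progress = FALSE)
    }
    logf("kinetics: %d tiles, %d classified", nrow(tk),
         sum(tk$class != "unclassified"))
  }

  if ("contexts" %in% stages) {
    prof <- context_methylation_profile(cpg, assignment, fx$annotations, lambda)
    outputs$context_profile <- file.path(out_dir, "context_profile.tsv")
    readr::write_tsv(prof, outputs$context_profile, progress = FALSE)
    masked <- mask_active_regions(cpg, assignment, fx$annotations,
                                  lambda_contig = lambda)
    outputs$masked_means <- file.path(out_dir, "masked_means.tsv")
    readr::write_tsv(masked, outputs$masked_means, progress = FALSE)
    if (!is.null(fx$expression) && !is.null(fx$gene_models)) {
      tc <- expression_tertile_analysis(
        fx$expression[fx$expression$cell_id %in% keep, ],
        cpg, assignment, fx$gene_models)
      outputs$tertile_tests <- file.path(out_dir, "tertile_tests.tsv")
      readr::write_tsv(tc$tests, outputs$tertile_tests, progress = FALSE)
    }
    logf("contexts: %d categories profiled", dplyr::n_distinct(prof$category))
  }

  if ("noncg" %in% stages) {
    calls <- fx$calls[fx$calls$cell_id %in% keep, ]
    mp <- noncg_motif_profile(calls, assignment, lambda)
    outputs$motif_fractions <- file.path(out_dir, "motif_fractions.tsv")
    readr::write_tsv(mp$fractions, outputs$motif_fractions, progress = FALSE)
    outputs$motif_profile <- file.path(out_dir, "motif_profile.tsv")
    readr::write_tsv(mp$motifs, outputs$motif_profile, progress = FALSE)
    logf("noncg: motif profile over %d groups",
         dplyr::n_distinct(mp$fractions$group))
  }

  invisible(outputs)
}

# read an emitted fixture directory back through the package readers
load_fixture <- function(dir, flank_size = 2000) {
  ss_path <- file.path(dir, "sample_sheet.tsv")
  if (!file.exists(ss_path)) abort_param(paste0("no sample sheet under ", dir))
  sheet <- read_sample_sheet(ss_path)
  fa <- file.path(dir, "genome.fa")
  seqs <- if (file.exists(fa)) load_sequences(fa) else NULL
  calls <- purrr::map_dfr(seq_len(nrow(sheet)), function(i) {
    read_cytosine_report(file.path(dir, sheet$call_file[i]),
                         dialect = "cytosine_report",
                         cell_id = sheet$cell_id[i])
  })
  bed_files <- list.files(file.path(dir, "beds"), pattern = "\\.bed$",
                          full.names = TRUE)
  names(bed_files) <- sub("\\.bed$", "", basename(bed_files))
  lambda <- "lambda"
  chrom_sizes <- NULL
  if (!is.null(seqs)) {
    chrom_sizes <- stats::setNames(nchar(seqs), names(seqs))
    chrom_sizes <- chrom_sizes[names(chrom_sizes) != lambda]
  }
  annotations <- if (length(bed_files) > 0) {
    read_bed_annotations(bed_files, chrom_sizes, flank_size)
  } else NULL
  gene_models <- NULL
  if (!is.null(annotations) &&
        all(c("gene", "promoter") %in% annotations$category)) {
    g <- annotations[annotations$category == "gene", ]
    p <- annotations[annotations$category == "promoter", ]
    gene_models <- dplyr::inner_join(
      g |> dplyr::select(gene_id = "name", "chrom", "start", "end"),
      p |> dplyr::select(gene_id = "name", promoter_start = "start",
                         promoter_end = "end"),
      by = "gene_id")
  }
  expr_path <- file.path(dir, "expression.tsv")
  list(
    sheet = sheet, calls = calls, cpg = merge_cpg_strands(calls),
    annotations = annotations, gene_models = gene_models,
    chrom_sizes = chrom_sizes,
    genome_cpg_count = if (!is.null(seqs))
      count_cpg_dyads(seqs, lambda) else NA_integer_,
    expression = if (file.exists(expr_path)) read_expression(expr_path) else NULL
  )
}
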