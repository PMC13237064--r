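#' Generator configuration for a toy annotated genome
#'
#' Returns the default parameters of the synthetic genome builder. The toy
#' genome mimics the structural vocabulary needed by the downstream
#' analyses: gene bodies with exons/introns and upstream promoters, CpG
#' islands (CpG-dense relative to background), promoter ATAC peaks whose
#' width encodes planted accessibility (fast > intermediate > slow gene
#' classes), LINE/LTR repeat intervals, maternally methylated imprinted
#' DMRs (CpG-dense so that single cells cover enough sites to be flagged),
#' and an unmethylated lambda spike-in contig carrying no annotation.
#'
#' Kinetic classes (fast/intermediate/slow) are planted on fixed-size
#' genome tiles; the three classes are assigned in the same ascending
#' three-way split sizes that the tile classifier uses, so class labels
#' are recoverable by a tertile rule when all tiles are scored. Genes are
#' placed preferentially into fast tiles (weights `gene_class_weights`),
#' which plants the genic-faster-than-intergenic signal.
#'
#' @param chrom_sizes named integer vector of genomic chromosome lengths (bp).
#' @param seed integer seed; the builder is deterministic given the config.
#' @param ... overrides for any default listed below.
#' @return a list of generator parameters.
#' @export
genome_config <- function(chrom_sizes = c(chr1 = 2e6), seed = 1, ...) {
  cfg <- list(
    chrom_sizes = chrom_sizes,
    seed = seed,
    lambda_contig = "lambda",
    lambda_size = 48502L,
    plant_tile_size = 1e5,
    n_genes = 20L,
    gene_length_range = c(10e3, 30e3),
    n_exons_range = c(3L, 8L),
    exon_length_range = c(200, 1000),
    promoter_size = 1000L,
    cgi_promoter_fraction = 0.5,
    n_orphan_cgi = 5L,
    cgi_length_range = c(500, 1500),
    cgi_cpg_density = 0.12,
    background_cpg_density = 0.02,
    atac_width = c(fast = 600L, intermediate = 400L, slow = 200L),
    n_line = 15L,
    n_ltr = 10L,
    repeat_length_range = c(1000, 5000),
    imprint_dmr_names = c("MEST", "RB1", "PLAGL1"),
    dmr_length = 2000L,
    flank_size = 2000L,
    gene_class_weights = c(fast = 3, intermediate = 2, slow = 1)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort_param(paste0("unknown genome_config parameter(s): ",
                       paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}

# Random sequence in which every CpG dyad is planted explicitly: background
# bases are sampled uniformly and any accidental C->G adjacency is broken,
# then "CG" dyads are planted at odd offsets at the requested density
# (higher inside `rich` intervals, 0-based half-open). This gives exact
# control of local CpG density.
rand_chrom_seq <- function(len, bg_density, rich = NULL, rich_density = bg_density) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  acc <- which(bases[-len] == "C" & bases[-1] == "G")
  if (length(acc) > 0) bases[acc + 1L] <- "A"
  rich_mask <- rep(FALSE, len)
  if (!is.null(rich) && nrow(rich) > 0) {
    for (i in seq_len(nrow(rich))) {
      rich_mask[(rich$start[i] + 1L):rich$end[i]] <- TRUE
    }
  }
  plant <- function(cand, density) {
    n <- round(length(cand) * 2 * density)  # cand holds every other offset
    if (n == 0 || length(cand) == 0) return(integer(0))
    sample(cand, min(n, length(cand)))
  }
  odd <- seq(1L, len - 1L, by = 2L)
  p_bg <- plant(odd[!rich_mask[odd]], bg_density)
  p_rich <- plant(odd[rich_mask[odd]], rich_density)
  p <- c(p_bg, p_rich)
  bases[p] <- "C"
  bases[p + 1L] <- "G"
  paste(bases, collapse = "")
}

place_nonoverlapping <- function(n, lengths, chrom_sizes, occupied, max_try = 200L,
                                 what = "interval") {
  out <- vector("list", n)
  occ <- occupied
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      chrom <- sample(names(chrom_sizes), 1L,
                      prob = as.numeric(chrom_sizes) / sum(as.numeric(chrom_sizes)))
      L <- chrom_sizes[[chrom]]
      w <- lengths[i]
      if (L <= w + 2) next
      s <- sample.int(L - w - 1L, 1L)
      cand <- tibble::tibble(chrom = chrom, start = s, end = s + w)
      if (!any(occ$chrom == chrom & occ$start < cand$end & occ$end > cand$start)) {
        out[[i]] <- cand
        occ <- dplyr::bind_rows(occ, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort_param(sprintf(
        "capacity error: could not place %s %d of %d without overlap; reduce counts or enlarge chromosomes",
        what, i, n))
    }
  }
  dplyr::bind_rows(out)
}

#' Build a synthetic annotated genome
#'
#' Deterministically (for a fixed config seed) generates chromosome
#' sequences with controlled CpG density, plants per-tile kinetic classes,
#' places gene models with promoters/exons/introns, CpG islands, promoter
#' ATAC peaks, LINE/LTR repeats and imprinted DMRs, and derives the
#' flanking/intergenic categories. The lambda spike-in contig is generated
#' but carries no annotation and is excluded from all genomic statistics
#' downstream.
#'
#' @param config list from [genome_config()].
#' @return an object of class `sim_genome`: a list with `chrom_sizes`,
#'   `lambda_contig`, `sequence` (named character, one string per contig,
#'   lambda included), `annotations` (tibble: category, chrom, start, end,
#'   name, score; 0-based half-open), `gene_models`, `tiles` (planted truth)
#'   and the `config`.
#' @export
build_genome <- function(config = genome_config()) {
  set.seed(config$seed)
  chrom_sizes <- vapply(config$chrom_sizes, as.integer, integer(1))
  tile <- as.integer(config$plant_tile_size)
  if (any(chrom_sizes < 2L * tile)) {
    abort_param("each chromosome must span at least two planting tiles")
  }

  # --- planted kinetic classes on tiles -------------------------------
  tiles <- purrr::imap_dfr(as.list(chrom_sizes), function(L, chrom) {
    starts <- seq(0L, L - 1L, by = tile)
    tibble::tibble(chrom = chrom, start = starts,
                   end = pmin(starts + tile, L))
  })
  sizes <- tertile_sizes(nrow(tiles))
  classes <- sample(rep(c("slow", "intermediate", "fast"), times = sizes))
  tiles$class <- classes
  tiles$tile_id <- sprintf("%s:%d-%d", tiles$chrom, tiles$start, tiles$end)

  # --- gene placement: weighted toward fast tiles ---------------------
  w <- config$gene_class_weights[tiles$class]
  prom <- as.integer(config$promoter_size)
  genes <- vector("list", config$n_genes)
  occupied <- tibble::tibble(chrom = character(), start = integer(), end = integer())
  for (i in seq_len(config$n_genes)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      ti <- sample.int(nrow(tiles), 1L, prob = w)
      glen <- round(stats::runif(1, config$gene_length_range[1],
                                 config$gene_length_range[2]))
      lo <- tiles$start[ti] + prom
      hi <- tiles$end[ti] - glen
      if (hi <= lo) next
      s <- sample(seq.int(lo, hi), 1L)
      cand <- tibble::tibble(chrom = tiles$chrom[ti],
                             start = s - prom, end = s + glen)
      if (!any(occupied$chrom == cand$chrom & occupied$start < cand$end &
                 occupied$end > cand$start)) {
        genes[[i]] <- tibble::tibble(
          gene_id = sprintf("gene%03d", i),
          chrom = tiles$chrom[ti], start = s, end = s + glen, strand = "+",
          promoter_start = s - prom, promoter_end = s,
          kinetic_class = tiles$class[ti],
          expression_tier = c(fast = "high", intermediate = "mid",
                              slow = "low")[[tiles$class[ti]]]
        )
        occupied <- dplyr::bind_rows(occupied, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort_param(sprintf(
        "capacity error: could not place gene %d of %d; reduce n_genes or enlarge chromosomes",
        i, config$n_genes))
    }
  }
  gene_models <- dplyr::bind_rows(genes)

  # --- exons/introns ---------------------------------------------------
  exon_rows <- purrr::pmap_dfr(gene_models, function(gene_id, chrom, start, end, ...) {
    n_ex <- sample(seq.int(config$n_exons_range[1], config$n_exons_range[2]), 1L)
    slot <- floor((end - start) / n_ex)
    purrr::map_dfr(seq_len(n_ex), function(k) {
      elen <- min(round(stats::runif(1, config$exon_length_range[1],
                                     config$exon_length_range[2])),
                  slot - 2L)
      s0 <- start + (k - 1L) * slot
      s <- s0 + sample.int(slot - elen, 1L) - 1L
      tibble::tibble(category = "exon", chrom = chrom, start = s, end = s + elen,
                     name = gene_id, score = 0)
    })
  })
  intron_rows <- gene_models |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_map(~{
      ex <- exon_rows[exon_rows$name == .y$gene_id[1], ] |> dplyr::arrange(.data$start)
      body <- .x
      gaps <- tibble::tibble(
        start = c(body$start, ex$end),
        end = c(ex$start, body$end)
      ) |> dplyr::filter(.data$start < .data$end)
      tibble::tibble(category = "intron", chrom = body$chrom,
                     start = gaps$start, end = gaps$end,
                     name = .y$gene_id[1], score = 0)
    }, .keep = FALSE) |>
    dplyr::bind_rows()

  promoter_rows <- gene_models |>
    dplyr::transmute(category = "promoter", chrom = .data$chrom,
                     start = .data$promoter_start, end = .data$promoter_end,
                     name = .data$gene_id, score = 0)
  gene_rows <- gene_models |>
    dplyr::transmute(category = "gene", chrom = .data$chrom, start = .data$start,
                     end = .data$end, name = .data$gene_id, score = 0)

  # --- CpG islands: at a fraction of promoters plus orphans -----------
  n_cgi_prom <- round(nrow(gene_models) * config$cgi_promoter_fraction)
  cgi_prom_idx <- sample.int(nrow(gene_models), n_cgi_prom)
  cgi_prom <- purrr::map_dfr(cgi_prom_idx, function(i) {
    g <- gene_models[i, ]
    len <- round(stats::runif(1, config$cgi_length_range[1], config$cgi_length_range[2]))
    center <- floor((g$promoter_start + g$promoter_end) / 2)
    s <- max(0L, center - floor(len / 2))
    tibble::tibble(category = "cgi", chrom = g$chrom, start = s,
                   end = min(s + len, chrom_sizes[[g$chrom]]),
                   name = paste0("cgi_", g$gene_id), score = 0)
  })
  orphan_len <- round(stats::runif(config$n_orphan_cgi,
                                   config$cgi_length_range[1],
                                   config$cgi_length_range[2]))
  occ_all <- dplyr::bind_rows(occupied, cgi_prom[, c("chrom", "start", "end")])
  orphan <- place_nonoverlapping(config$n_orphan_cgi, orphan_len, chrom_sizes,
                                 occ_all, what = "orphan CpG island")
  cgi_rows <- dplyr::bind_rows(
    cgi_prom,
    orphan |> dplyr::mutate(category = "cgi",
                            name = sprintf("cgi_orphan%02d", dplyr::row_number()),
                            score = 0)
  )

  # --- promoter ATAC peaks: width encodes planted accessibility -------
  atac_rows <- purrr::pmap_dfr(gene_models, function(gene_id, chrom, promoter_start,
                                                     promoter_end, kinetic_class, ...) {
    wdt <- as.integer(config$atac_width[[kinetic_class]])
    center <- floor((promoter_start + promoter_end) / 2)
    s <- max(0L, center - wdt %/% 2L)
    tibble::tibble(category = "atac_peak", chrom = chrom, start = s, end = s + wdt,
                   name = paste0("peak_", gene_id), score = wdt / 100)
  })

  # --- repeats and imprinted DMRs -------------------------------------
  occ_all <- dplyr::bind_rows(occ_all, atac_rows[, c("chrom", "start", "end")])
  rep_len <- round(stats::runif(config$n_line + config$n_ltr,
                                config$repeat_length_range[1],
                                config$repeat_length_range[2]))
  reps <- place_nonoverlapping(config$n_line + config$n_ltr, rep_len,
                               chrom_sizes, occ_all, what = "repeat")
  reps$category <- rep(c("line", "ltr"), times = c(config$n_line, config$n_ltr))
  reps$name <- paste0(reps$category, seq_len(nrow(reps)))
  reps$score <- 0
  occ_all <- dplyr::bind_rows(occ_all, reps[, c("chrom", "start", "end")])

  n_dmr <- length(config$imprint_dmr_names)
  dmrs <- place_nonoverlapping(n_dmr, rep(config$dmr_length, n_dmr),
                               chrom_sizes, occ_all, what = "imprinted DMR")
  dmrs$category <- "imprint_dmr"
  dmrs$name <- config$imprint_dmr_names
  dmrs$score <- 0

  annotations <- dplyr::bind_rows(gene_rows, exon_rows, intron_rows,
                                  promoter_rows, cgi_rows, atac_rows,
                                  reps, dmrs) |>
    dplyr::select("category", "chrom", "start", "end", "name", "score")

  # --- derived categories: flanking and intergenic --------------------
  annotations <- dplyr::bind_rows(
    annotations,
    derive_flanking(gene_rows, chrom_sizes, config$flank_size),
    derive_intergenic(gene_rows, chrom_sizes, config$flank_size)
  )

  # --- sequence: CpG-rich inside cgi and imprinted DMRs ---------------
  rich <- annotations |>
    dplyr::filter(.data$category %in% c("cgi", "imprint_dmr")) |>
    dplyr::select("chrom", "start", "end")
  sequence <- purrr::imap(as.list(chrom_sizes), function(L, chrom) {
    rand_chrom_seq(L, config$background_cpg_density,
                   rich = rich[rich$chrom == chrom, ],
                   rich_density = config$cgi_cpg_density)
  })
  sequence[[config$lambda_contig]] <-
    rand_chrom_seq(config$lambda_size, config$background_cpg_density)

  structure(
    list(chrom_sizes = chrom_sizes,
         lambda_contig = config$lambda_contig,
         sequence = sequence,
         annotations = annotations,
         gene_models = gene_models,
         tiles = tiles[, c("tile_id", "chrom", "start", "end", "class")],
         config = config),
    class = "sim_genome"
  )
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome> ", length(x$chrom_sizes), " chromosome(s), ",
      sum(as.numeric(x$chrom_sizes)), " bp + lambda spike-in (",
      nchar(x$sequence[[x$lambda_contig]]), " bp)\n", sep = "")
  cat("  genes: ", nrow(x$gene_models), "; planted tiles: ", nrow(x$tiles),
      " (", paste(table(x$tiles$class)[c("fast", "intermediate", "slow")],
                  collapse = "/"), " fast/int/slow)\n", sep = "")
  invisible(x)
}

#' Flanking intervals of gene bodies
#'
#' The +/- `flank_size` bp around each gene body, with gene-body footprint
#' removed, clipped to chromosome bounds.
#'
#' @param genes interval tibble of gene bodies (chrom/start/end, 0-based).
#' @param chrom_sizes named lengths.
#' @param flank_size bp on each side.
#' @return tibble with category "flanking".
#' @export
derive_flanking <- function(genes, chrom_sizes, flank_size = 2000) {
  check_interval_tbl(genes, "gene table")
  if (nrow(genes) == 0) {
    return(tibble::tibble(category = character(), chrom = character(),
                          start = integer(), end = integer(),
                          name = character(), score = numeric()))
  }
  ext <- genes |>
    dplyr::mutate(start = pmax(0L, .data$start - as.integer(flank_size)),
                  end = pmin(unname(chrom_sizes[.data$chrom]),
                             .data$end + as.integer(flank_size)))
  body_gr <- GenomicRanges::reduce(intervals_to_gr(genes))
  ext_gr <- GenomicRanges::reduce(intervals_to_gr(ext))
  fl <- GenomicRanges::setdiff(ext_gr, body_gr)
  tibble::tibble(category = "flanking",
                 chrom = as.character(GenomicRanges::seqnames(fl)),
                 start = GenomicRanges::start(fl) - 1L,
                 end = GenomicRanges::end(fl),
                 name = paste0("flank", seq_along(fl)), score = 0)
}

#' Intergenic intervals
#'
#' Complement of gene bodies extended by `flank_size` (so intergenic and
#' flanking are disjoint categories, matching the usual genic / flanking /
#' intergenic trichotomy).
#'
#' @inheritParams derive_flanking
#' @return tibble with category "intergenic".
#' @export
derive_intergenic <- function(genes, chrom_sizes, flank_size = 2000) {
  check_interval_tbl(genes, "gene table")
  full <- tibble::tibble(chrom = names(chrom_sizes), start = 0L,
                         end = as.integer(unname(chrom_sizes)))
  if (nrow(genes) == 0) {
    out <- full
  } else {
    ext <- genes |>
      dplyr::mutate(start = pmax(0L, .data$start - as.integer(flank_size)),
                    end = pmin(unname(chrom_sizes[.data$chrom]),
                               .data$end + as.integer(flank_size)))
    gr <- GenomicRanges::setdiff(intervals_to_gr(full),
                                 GenomicRanges::reduce(intervals_to_gr(ext)))
    out <- tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                          start = GenomicRanges::start(gr) - 1L,
                          end = GenomicRanges::end(gr))
  }
  out |>
    dplyr::mutate(category = "intergenic",
                  name = paste0("intergenic", dplyr::row_number()), score = 0) |>
    dplyr::select("category", "chrom", "start", "end", "name", "score")
}

#' Number of CpG dyads in the reference (spike-in excluded)
#' @param genome a `sim_genome`, or a named character vector of sequences.
#' @param lambda_contig contig name to exclude.
#' @return integer dyad count.
#' @export
count_cpg_dyads <- function(genome, lambda_contig = NULL) {
  seqs <- if (inherits(genome, "sim_genome")) {
    lambda_contig <- genome$lambda_contig
    genome$sequence
  } else genome
  use <- setdiff(names(seqs), lambda_contig)
  sum(vapply(seqs[use], function(s) {
    length(Biostrings::matchPattern("CG", Biostrings::DNAString(s)))
  }, integer(1)))
}

#' Write genome FASTA
#' @param genome `sim_genome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome$sequence))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Write per-category BED6 annotation files
#' @param genome `sim_genome`.
#' @param dir output directory (created if absent).
#' @return named character vector of paths (category -> file).
#' @export
write_annotation_beds <- function(genome, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cats <- sort(unique(genome$annotations$category))
  paths <- vapply(cats, function(cat) {
    tbl <- genome$annotations |>
      dplyr::filter(.data$category == cat) |>
      dplyr::arrange(.data$chrom, .data$start) |>
      dplyr::transmute(.data$chrom, .data$start, .data$end, .data$name,
                       .data$score, strand = ".")
    p <- file.path(dir, paste0(cat, ".bed"))
    readr::write_tsv(tbl, p, col_names = FALSE, progress = FALSE)
    p
  }, character(1))
  paths
}
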