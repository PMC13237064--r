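#' Kinetic model for synthetic methylomes
#'
#' Forward model of gradual de novo CpG methylation along a latent
#' developmental progression \eqn{\tau \in [0,1]}. Each planted kinetic
#' class follows a piecewise-linear gain curve
#' \deqn{m(\tau) = \min(\mathrm{ceiling},\; r_{early}\min(\tau, 1/2) +
#'   r_{late}\max(\tau - 1/2, 0))}
#' with fast classes gaining early and slow classes late, matching the
#' gradual (not switch-like) acquisition pattern in developing
#' prospermatogonia. Active regulatory regions (promoters, CpG islands,
#' ATAC peaks) stay at `active_region_level`; imprinted DMRs stay at 0 in
#' germ cells and at 0.5 in somatic cells, which also carry a uniformly
#' high somatic methylome elsewhere.
#'
#' Bisulfite conversion failure is one-sided: an unmethylated cytosine is
#' read as methylated with probability `1 - conversion_rate`, so the
#' observed methylated-call probability at true level m is
#' \eqn{m + (1-m)(1-c)}. Over-conversion of 5mC is not modeled.
#'
#' CH (non-CpG) methylation rises linearly with \eqn{\tau} from `ch_base`
#' to `ch_base + ch_slope`, and is distributed over the twelve CH
#' trinucleotides so that the motif distribution of methylated calls
#' equals `ch_motif_weights` (CAC and CAG elevated, as expected for
#' DNMT3A/DNMT3B targets).
#'
#' @param ... overrides for any default component.
#' @return a list of class `kinetic_model`.
#' @export
kinetic_model <- function(...) {
  ch_w <- c(CAC = 0.30, CAG = 0.25,
            CAA = 0.045, CAT = 0.045,
            CCA = 0.045, CCC = 0.045, CCG = 0.045, CCT = 0.045,
            CTA = 0.045, CTC = 0.045, CTG = 0.045, CTT = 0.045)
  mod <- list(
    class_rates = list(fast = c(early = 1.5, late = 0.2),
                       intermediate = c(early = 0.9, late = 0.6),
                       slow = c(early = 0.4, late = 1.0)),
    ceiling = c(fast = 0.85, intermediate = 0.75, slow = 0.65),
    active_region_level = 0,
    somatic_level = 0.75,
    imprint_somatic_level = 0.5,
    ch_base = 0.0005,
    ch_slope = 0.004,
    ch_motif_weights = ch_w / sum(ch_w),
    conversion_rate = 0.993,
    somatic_fraction = 0.01,
    mitotic_fraction = 0.12,
    maintenance = TRUE,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(mod))
  if (length(unknown) > 0) {
    abort_param(paste0("unknown kinetic_model parameter(s): ",
                       paste(unknown, collapse = ", ")))
  }
  mod[names(dots)] <- dots
  stopifnot(mod$conversion_rate > 0, mod$conversion_rate <= 1,
            all(mod$ceiling >= 0), all(mod$ceiling <= 1))
  if (abs(sum(mod$ch_motif_weights) - 1) > 1e-8) {
    abort_param("ch_motif_weights must sum to 1 over CAN, CCN, CTN")
  }
  if (mod$class_rates$fast[["early"]] <= mod$class_rates$slow[["early"]]) {
    abort_param("fast class must have a larger early gain rate than slow")
  }
  class(mod) <- "kinetic_model"
  mod
}

#' True methylation level of a kinetic class at progression tau
#'
#' The noiseless class curve, before conversion error. Vectorized over
#' `tau`.
#'
#' @param model `kinetic_model`.
#' @param class "fast", "intermediate" or "slow".
#' @param tau progression in `[0, 1]`.
#' @return numeric levels in `[0, 1]`.
#' @export
expected_methylation <- function(model, class, tau) {
  r <- model$class_rates[[class]]
  if (is.null(r)) abort_param(paste0("unknown kinetic class: ", class))
  pmin(model$ceiling[[class]],
       r[["early"]] * pmin(tau, 0.5) + r[["late"]] * pmax(tau - 0.5, 0))
}

#' Table of CpG dyads in a synthetic genome
#'
#' One row per CpG dyad, keyed by the 1-based position of the + strand C,
#' with trinucleotide contexts on both strands, planted tile class,
#' active-region / imprinted-DMR membership and the spike-in flag.
#'
#' @param genome `sim_genome`.
#' @return tibble: chrom, pos, trinuc_plus, trinuc_minus, tile_class,
#'   active, imprint, lambda.
#' @export
cpg_dyad_table <- function(genome) {
  per_chrom <- purrr::imap(genome$sequence, function(s, chrom) {
    p <- Biostrings::start(Biostrings::matchPattern("CG", Biostrings::DNAString(s)))
    if (length(p) == 0) return(NULL)
    padded <- paste0("N", s, "N")  # shift +1: position i of s is i+1 of padded
    tibble::tibble(
      chrom = chrom, pos = p,
      trinuc_plus = substring(padded, p + 1L, p + 3L),
      trinuc_minus = reverse_complement(substring(padded, p, p + 2L))
    )
  })
  tbl <- dplyr::bind_rows(per_chrom)
  ann <- genome$annotations
  active <- ann[ann$category %in% c("promoter", "cgi", "atac_peak"), ]
  dmr <- ann[ann$category == "imprint_dmr", ]
  tbl |>
    dplyr::mutate(
      lambda = .data$chrom == genome$lambda_contig,
      active = sites_in_intervals(.data$chrom, .data$pos, active) & !.data$lambda,
      imprint = sites_in_intervals(.data$chrom, .data$pos, dmr) & !.data$lambda,
      tile_class = assign_tile_class(.data$chrom, .data$pos, genome$tiles)
    )
}

assign_tile_class <- function(chrom, pos, tiles) {
  size <- tiles$end[1] - tiles$start[1]
  key <- paste0(chrom, ":", (pos - 1L) %/% size)
  tile_key <- paste0(tiles$chrom, ":", tiles$start %/% size)
  unname(stats::setNames(tiles$class, tile_key)[key])
}

#' Table of CH (non-CpG cytosine) sites in a synthetic genome
#'
#' Per-strand CH cytosines with trinucleotide context on the C strand.
#' The spike-in contig is included (flagged) so that conversion-rate
#' estimation sees all-context lambda calls.
#'
#' @param genome `sim_genome`.
#' @return tibble: chrom, pos (1-based on the C strand), strand, trinuc,
#'   context (CHG/CHH), lambda.
#' @export
ch_site_table <- function(genome) {
  per_chrom <- purrr::imap(genome$sequence, function(s, chrom) {
    padded <- paste0("NN", s, "NN")  # position i of s is i+2 of padded
    cpos <- Biostrings::start(Biostrings::matchPattern("C", Biostrings::DNAString(s)))
    plus_tri <- substring(padded, cpos + 2L, cpos + 4L)
    keep <- substr(plus_tri, 2, 2) != "G" & !grepl("N", plus_tri, fixed = TRUE)
    plus <- tibble::tibble(chrom = chrom, pos = cpos[keep], strand = "+",
                           trinuc = plus_tri[keep])
    gpos <- Biostrings::start(Biostrings::matchPattern("G", Biostrings::DNAString(s)))
    minus_tri <- reverse_complement(substring(padded, gpos, gpos + 2L))
    keep <- substr(minus_tri, 2, 2) != "G" & !grepl("N", minus_tri, fixed = TRUE)
    minus <- tibble::tibble(chrom = chrom, pos = gpos[keep], strand = "-",
                            trinuc = minus_tri[keep])
    dplyr::bind_rows(plus, minus)
  })
  dplyr::bind_rows(per_chrom) |>
    dplyr::mutate(context = context_of_trinuc(.data$trinuc),
                  lambda = .data$chrom == genome$lambda_contig)
}

#' True per-dyad methylation levels for a cell
#'
#' The analytic expectation used as an oracle in tests: class curves by
#' planted tile class, overridden by active regions, imprinted DMRs and
#' the spike-in; somatic cells get 0.5 at imprinted DMRs and a uniform
#' somatic level elsewhere.
#'
#' @param dyads tibble from [cpg_dyad_table()].
#' @param model `kinetic_model`.
#' @param tau progression of the cell.
#' @param type "germ" or "somatic".
#' @return numeric vector of true levels, one per dyad row.
#' @export
true_dyad_levels <- function(dyads, model, tau, type = "germ") {
  m <- numeric(nrow(dyads))
  if (type == "somatic") {
    m[] <- model$somatic_level
    m[dyads$imprint] <- model$imprint_somatic_level
    m[dyads$active] <- model$active_region_level
  } else {
    for (cl in names(model$class_rates)) {
      idx <- which(dyads$tile_class == cl & !dyads$lambda)
      m[idx] <- expected_methylation(model, cl, tau)
    }
    m[dyads$active] <- model$active_region_level
    m[dyads$imprint] <- 0
  }
  m[dyads$lambda] <- 0
  m
}

#' Expected global CpG methylation of a germ cell at progression tau
#'
#' Mean of [true_dyad_levels()] over all genomic dyads (spike-in
#' excluded); monotone non-decreasing in `tau`.
#'
#' @param genome `sim_genome`.
#' @param model `kinetic_model`.
#' @param tau numeric vector of progressions.
#' @param dyads optional precomputed [cpg_dyad_table()].
#' @return numeric vector, one expected level per `tau`.
#' @export
expected_global_methylation <- function(genome, model, tau, dyads = NULL) {
  dyads <- dyads %||% cpg_dyad_table(genome)
  dyads <- dyads[!dyads$lambda, ]
  vapply(tau, function(t) mean(true_dyad_levels(dyads, model, t)), numeric(1))
}

stage_labels <- c("1d", "2w", "1.1m", "2.5m", "3.4m", "4m",
                  "5m", "6.4m", "8.5m", "12.5m")

#' Simulate a cohort of single-cell methylomes
#'
#' Draws cells along a latent uniform progression, emits per-cytosine
#' methylation calls (CpG dyads per strand, subsampled CH sites, and
#' unmethylated lambda spike-in calls) under the kinetic model with
#' one-sided conversion error, and draws a matched expression table
#' (gene tiers planted by kinetic class, cell-cycle genes and a
#' DNMT1-like maintenance marker expressed in the mitotic fraction).
#'
#' @param genome `sim_genome`.
#' @param model `kinetic_model`; `model$seed` seeds all randomness.
#' @param n_cells number of cells (ignored when `cell_plan` is given).
#' @param depth mean calls per covered cytosine strand; each covered
#'   strand gets `1 + rpois(depth - 1)` calls.
#' @param coverage_fraction fraction of genomic CpG dyads observed per
#'   cell, in (0, 1].
#' @param ch_coverage_fraction fraction of CH sites observed per cell
#'   (0 skips CH simulation).
#' @param lambda_calls number of spike-in cytosine calls per cell.
#' @param cell_plan optional tibble overriding the cell roster; columns
#'   `cell_id`, `tau`, `type` ("germ"/"somatic"), and optionally
#'   `mitotic`, `coverage_fraction`, `mapping_rate`.
#' @return list of class `sim_cohort`: `calls` (per-cell cytosine call
#'   tibble), `cpg` (strand-merged dyad tibble), `sheet` (sample sheet),
#'   `expression` (long tibble gene_id/cell_id/count), `cell_truth`,
#'   `genome`, `model`.
#' @export
simulate_cells <- function(genome, model = kinetic_model(), n_cells = 60,
                           depth = 1, coverage_fraction = 0.2,
                           ch_coverage_fraction = 0.05, lambda_calls = 5000,
                           cell_plan = NULL) {
  if (is.null(cell_plan) && (is.na(n_cells) || n_cells < 1)) {
    abort_param("n_cells must be >= 1")
  }
  if (coverage_fraction <= 0 || coverage_fraction > 1) {
    abort_param("coverage_fraction must be in (0, 1]")
  }
  if (depth < 1) abort_param("depth must be >= 1")
  set.seed(model$seed)

  dyads <- cpg_dyad_table(genome)
  gen_dyads <- dyads[!dyads$lambda, ]
  lam_seq <- genome$sequence[[genome$lambda_contig]]
  lam_sites <- lambda_cytosines(lam_seq, genome$lambda_contig)
  ch <- NULL
  ch_freq <- NULL
  if (ch_coverage_fraction > 0) {
    ch <- ch_site_table(genome)
    ch <- ch[!ch$lambda, ]
    ch_freq <- table(ch$trinuc)[names(model$ch_motif_weights)]
    ch_freq <- as.numeric(ch_freq) / nrow(ch)
    names(ch_freq) <- names(model$ch_motif_weights)
  }

  cells <- cell_plan %||% default_cell_plan(n_cells, model)
  if (anyDuplicated(cells$cell_id)) abort_param("duplicate cell_id in cell plan")
  if (!"mitotic" %in% names(cells)) cells$mitotic <- FALSE
  if (!"coverage_fraction" %in% names(cells)) {
    cells$coverage_fraction <- coverage_fraction
  }
  if (!"mapping_rate" %in% names(cells)) {
    cells$mapping_rate <- stats::runif(nrow(cells), 0.6, 0.9)
  }
  cells$stage <- stage_labels[pmin(10L, 1L + floor(cells$tau * 10))]

  call_list <- purrr::pmap(cells, function(cell_id, tau, type, mitotic,
                                           coverage_fraction, ...) {
    simulate_one_cell(cell_id, tau, type, mitotic, coverage_fraction,
                      gen_dyads, lam_sites, ch, ch_freq, model, depth,
                      ch_coverage_fraction, lambda_calls)
  })
  calls <- dplyr::bind_rows(call_list)
  cpg <- merge_cpg_strands(calls)

  expression <- simulate_expression(genome, cells)

  sheet <- cells |>
    dplyr::transmute(.data$cell_id, .data$stage, age = .data$tau,
                     .data$mapping_rate, call_file = NA_character_)

  structure(
    list(calls = calls, cpg = cpg, sheet = sheet, expression = expression,
         cell_truth = cells[, c("cell_id", "tau", "type", "mitotic", "stage")],
         genome = genome, model = model),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", nrow(x$sheet), " cells, ",
      nrow(x$calls), " cytosine call rows (",
      nrow(x$cpg), " merged CpG dyad rows)\n", sep = "")
  invisible(x)
}

default_cell_plan <- function(n_cells, model) {
  tau <- stats::runif(n_cells)
  type <- ifelse(stats::runif(n_cells) < model$somatic_fraction,
                 "somatic", "germ")
  mitotic <- type == "germ" & stats::runif(n_cells) < model$mitotic_fraction
  tibble::tibble(
    cell_id = sprintf("cell%03d", seq_len(n_cells)),
    tau = tau, type = type, mitotic = mitotic
  )
}

lambda_cytosines <- function(lam_seq, contig) {
  padded <- paste0("NN", lam_seq, "NN")
  cpos <- Biostrings::start(Biostrings::matchPattern("C", Biostrings::DNAString(lam_seq)))
  gpos <- Biostrings::start(Biostrings::matchPattern("G", Biostrings::DNAString(lam_seq)))
  plus <- tibble::tibble(chrom = contig, pos = cpos, strand = "+",
                         trinuc = substring(padded, cpos + 2L, cpos + 4L))
  minus <- tibble::tibble(chrom = contig, pos = gpos, strand = "-",
                          trinuc = reverse_complement(substring(padded, gpos, gpos + 2L)))
  dplyr::bind_rows(plus, minus) |>
    dplyr::filter(!grepl("N", .data$trinuc, fixed = TRUE)) |>
    dplyr::mutate(context = context_of_trinuc(.data$trinuc))
}

draw_depth <- function(n, depth) {
  if (depth <= 1) rep(1L, n) else 1L + stats::rpois(n, depth - 1)
}

simulate_one_cell <- function(cell_id, tau, type, mitotic, cov_frac,
                              gen_dyads, lam_sites, ch, ch_freq, model,
                              depth, ch_cov_frac, lambda_calls) {
  c_rate <- model$conversion_rate
  dilute <- if (!model$maintenance && isTRUE(mitotic)) 0.5 else 1

  # CpG dyads: per covered dyad, one or both strands observed
  covered <- which(stats::runif(nrow(gen_dyads)) < cov_frac)
  out <- NULL
  if (length(covered) > 0) {
    d <- gen_dyads[covered, ]
    m <- true_dyad_levels(d, model, tau, type) * dilute
    p_obs <- m + (1 - m) * (1 - c_rate)
    pat <- sample(c("+", "-", "both"), length(covered), replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    mk_strand <- function(sel, which_strand) {
      if (sum(sel) == 0) return(NULL)
      n_tot <- draw_depth(sum(sel), depth)
      plus <- which_strand == "+"
      tibble::tibble(
        cell_id = cell_id, chrom = d$chrom[sel],
        pos = if (plus) d$pos[sel] else d$pos[sel] + 1L,
        strand = which_strand, context = "CG",
        trinucleotide = if (plus) d$trinuc_plus[sel] else d$trinuc_minus[sel],
        n_meth = stats::rbinom(sum(sel), n_tot, p_obs[sel]),
        n_unmeth = NA_integer_, n_total = n_tot
      )
    }
    out <- dplyr::bind_rows(
      mk_strand(pat %in% c("+", "both"), "+"),
      mk_strand(pat %in% c("-", "both"), "-")
    )
  }

  # CH sites
  if (!is.null(ch) && ch_cov_frac > 0) {
    sel <- which(stats::runif(nrow(ch)) < ch_cov_frac)
    if (length(sel) > 0) {
      s <- ch[sel, ]
      level <- model$ch_base + model$ch_slope * tau
      if (type == "somatic") level <- model$ch_base
      q <- level * model$ch_motif_weights[s$trinuc] / ch_freq[s$trinuc]
      q <- pmin(unname(q), 1) * dilute
      p_obs <- q + (1 - q) * (1 - c_rate)
      n_tot <- draw_depth(length(sel), depth)
      out <- dplyr::bind_rows(out, tibble::tibble(
        cell_id = cell_id, chrom = s$chrom, pos = s$pos, strand = s$strand,
        context = s$context, trinucleotide = s$trinuc,
        n_meth = stats::rbinom(length(sel), n_tot, p_obs),
        n_unmeth = NA_integer_, n_total = n_tot
      ))
    }
  }

  # lambda spike-in: truly unmethylated, all contexts
  if (lambda_calls > 0) {
    sel <- sample.int(nrow(lam_sites), min(lambda_calls, nrow(lam_sites)))
    s <- lam_sites[sel, ]
    n_tot <- draw_depth(length(sel), depth)
    out <- dplyr::bind_rows(out, tibble::tibble(
      cell_id = cell_id, chrom = s$chrom, pos = s$pos, strand = s$strand,
      context = s$context, trinucleotide = s$trinuc,
      n_meth = stats::rbinom(length(sel), n_tot, 1 - c_rate),
      n_unmeth = NA_integer_, n_total = n_tot
    ))
  }

  if (is.null(out)) {
    return(tibble::tibble(cell_id = character(), chrom = character(),
                          pos = integer(), strand = character(),
                          context = character(), trinucleotide = character(),
                          n_meth = integer(), n_unmeth = integer()))
  }
  out$n_unmeth <- out$n_total - out$n_meth
  out$n_total <- NULL
  dplyr::arrange(out, .data$chrom, .data$pos, .data$strand)
}

# expression: planted tiers by kinetic class, a background gene
# complement (stabilizes library sizes and control-gene draws), cycle
# genes and a DNMT1-like maintenance marker expressed only in mitotic
# cells
simulate_expression <- function(genome, cells, n_background = 60) {
  tier_mu <- c(high = 50, mid = 10, low = 2)
  gm <- genome$gene_models
  cycle_genes <- sim_cycle_genes()
  bg_genes <- sprintf("BG%03d", seq_len(n_background))
  bg_mu <- stats::setNames(stats::rlnorm(n_background, log(5), 0.8), bg_genes)
  genes <- c(gm$gene_id, bg_genes, cycle_genes, "DNMT1")
  grid <- tidyr::expand_grid(gene_id = genes, cell_id = cells$cell_id)
  mitotic <- stats::setNames(cells$mitotic, cells$cell_id)
  mu_gene <- stats::setNames(tier_mu[gm$expression_tier], gm$gene_id)
  mu <- ifelse(grid$gene_id %in% gm$gene_id,
               mu_gene[grid$gene_id],
        ifelse(grid$gene_id %in% bg_genes,
               bg_mu[grid$gene_id],
        ifelse(grid$gene_id %in% cycle_genes,
               ifelse(mitotic[grid$cell_id], 30, 0.5),
               ifelse(mitotic[grid$cell_id], 25, 0.2))))
  grid$count <- stats::rnbinom(nrow(grid), mu = unname(mu), size = 2)
  grid
}

#' Planted cell-cycle gene set of the synthetic cohort
#' @return character vector of gene ids.
#' @export
sim_cycle_genes <- function() sprintf("CYC%02d", 1:10)
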