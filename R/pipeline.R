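#' Experiment grid configuration
#'
#' Describes the full factorial simulation experiment: for every
#' (read length, depth, replicate) cell, SNVs are planted in the MCR and
#' flank strata, a diploid genome is built, paired-end reads are simulated,
#' mapped with the unique-mapping filter, variants are called and the call
#' set is evaluated per stratum. Defaults mirror the study grid: read
#' lengths 75 and 150 bp, depths 10/30/50/100x, 20 replicates (160
#' datasets).
#'
#' @param genome An \code{mcr_genome}, or an \code{mcr_truth_build} (its
#'   genome is used).
#' @param read_lengths,depths Strategy grid.
#' @param replicates Replicates per strategy (>= 1).
#' @param snv_rate Per-base SNV rate within strata (default 0.001 = one
#'   per kb).
#' @param het_fraction Heterozygous fraction among planted SNVs.
#' @param error_rate,insert_mean,insert_sd Read-simulation parameters.
#' @param window Seed window length for MCR discovery.
#' @param k Mapper anchor k-mer length.
#' @param min_depth,min_alt_count,min_alt_frac,hom_frac Caller thresholds.
#' @param base_seed Base seed; each cell derives its own seed
#'   deterministically from (base seed, read length, depth, replicate).
#' @return An \code{mcr_experiment_config}.
#' @export
experiment_config <- function(genome, read_lengths = c(75L, 150L),
                              depths = c(10, 30, 50, 100),
                              replicates = 20L, snv_rate = 0.001,
                              het_fraction = 0.5, error_rate = 0.01,
                              insert_mean = 400, insert_sd = 50,
                              window = 300L, k = 31L, min_depth = 4L,
                              min_alt_count = 2L, min_alt_frac = 0.2,
                              hom_frac = 0.8, base_seed = 1L) {
  if (inherits(genome, "mcr_truth_build")) genome <- genome$genome
  stopifnot(inherits(genome, "mcr_genome"))
  if (length(read_lengths) == 0 || length(depths) == 0)
    stop("strategy grid must be non-empty")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(genome = genome, read_lengths = as.integer(read_lengths),
                 depths = depths, replicates = as.integer(replicates),
                 snv_rate = snv_rate, het_fraction = het_fraction,
                 error_rate = error_rate, insert_mean = insert_mean,
                 insert_sd = insert_sd, window = as.integer(window),
                 k = as.integer(k), min_depth = as.integer(min_depth),
                 min_alt_count = as.integer(min_alt_count),
                 min_alt_frac = min_alt_frac, hom_frac = hom_frac,
                 base_seed = as.integer(base_seed)),
            class = "mcr_experiment_config")
}

#' @export
print.mcr_experiment_config <- function(x, ...) {
  cat("<mcr_experiment_config> ",
      length(x$read_lengths) * length(x$depths), " strategies x ",
      x$replicates, " replicates = ",
      length(x$read_lengths) * length(x$depths) * x$replicates,
      " datasets\n", sep = "")
  invisible(x)
}

#' Run the full experiment grid
#'
#' Executes plant -> haplotype -> simulate -> map -> call -> evaluate for
#' every grid cell. The per-cell seed is a deterministic mix of the base
#' seed and the cell coordinates, so any cell can be recomputed
#' independently and a full rerun is bit-identical. When \code{out_dir} is
#' given, each cell's evaluation rows are written to
#' \code{cell_<strategy>_rep<i>.tsv} and existing files are reused
#' (resume); the manifest records each cell's seed, read counts and file
#' checksum.
#'
#' @param config An \code{mcr_experiment_config}.
#' @param mcr Optional \code{GRanges} of MCR intervals; when \code{NULL}
#'   they are discovered by [find_mcrs()] at the configured window.
#' @param out_dir Optional output directory for per-cell TSVs and the
#'   manifest.
#' @param verbose Print per-cell progress.
#' @return An \code{mcr_grid_result}: list with \code{report} (one row per
#'   cell x stratum), \code{manifest}, \code{strata} and \code{config}.
#' @export
run_experiment_grid <- function(config, mcr = NULL, out_dir = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(config, "mcr_experiment_config"))
  g <- config$genome
  if (is.null(mcr)) {
    mcr <- mcr_loci(find_mcrs(g, window = config$window))
    if (length(mcr) == 0)
      stop("no MCRs found in the genome; supply `mcr` explicitly")
  }
  strata <- define_strata(mcr, g)
  index <- build_index(g, k = config$k)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  report <- list(); manifest <- list()
  for (rl in config$read_lengths) {
    for (dp in config$depths) {
      strat <- sim_strategy(read_length = rl, depth = dp,
                            error_rate = config$error_rate,
                            insert_mean = config$insert_mean,
                            insert_sd = config$insert_sd)
      slab <- strategy_label(strat)
      for (rep in seq_len(config$replicates)) {
        cell_seed <- mix_seed(config$base_seed, rl, round(dp * 1000), rep)
        cell_id <- sprintf("cell_%s_rep%02d", slab, rep)
        cell_file <- if (!is.null(out_dir))
          file.path(out_dir, paste0(cell_id, ".tsv")) else NULL
        status <- "ok"
        if (!is.null(cell_file) && file.exists(cell_file)) {
          rows <- read.table(cell_file, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
          status <- "resumed"
        } else {
          rows <- tryCatch({
            run_grid_cell(g, strata, index, strat, config, cell_seed)
          }, error = function(e) {
            status <<- paste("error:", conditionMessage(e))
            NULL
          })
          if (!is.null(rows)) {
            rows <- cbind(strategy = slab, replicate = rep, rows,
                          stringsAsFactors = FALSE)
            if (!is.null(cell_file))
              write.table(rows, cell_file, sep = "\t", quote = FALSE,
                          row.names = FALSE)
          }
        }
        if (!is.null(rows)) report[[length(report) + 1L]] <- rows
        manifest[[length(manifest) + 1L]] <- data.frame(
          cell = cell_id, strategy = slab, replicate = rep,
          seed = cell_seed, status = status,
          checksum = if (!is.null(cell_file) && file.exists(cell_file))
            unname(tools::md5sum(cell_file)) else NA_character_,
          stringsAsFactors = FALSE)
        if (verbose) message(cell_id, " [", status, "]")
      }
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  structure(list(report = report, manifest = manifest, strata = strata,
                 config = config),
            class = "mcr_grid_result")
}

# One grid cell: plant -> haplotypes -> simulate -> map -> call -> evaluate.
# Simulation, mapping and pileup run through the fused native driver, which
# shares its cores with simulate_read_pairs()/map_read_pairs() and is
# bit-identical to that modular path for the same seed.
run_grid_cell <- function(g, strata, index, strat, config, cell_seed) {
  truth <- plant_snvs(strata, g, rate = config$snv_rate,
                      het_fraction = config$het_fraction,
                      seed = cell_seed)
  haps <- build_haplotypes(g, truth, seed = mix_seed(cell_seed, 2))
  max_frag <- strat$insert_mean + 4 * strat$insert_sd
  if (any(g$lengths < max_frag))
    stop("chromosome(s) shorter than the maximum fragment length")
  n_pairs <- as.integer(round(strat$depth * total_genome_length(g) /
                                (2 * strat$read_length)))
  pu <- cpp_pileup_new(unname(g$seq))
  stats <- cpp_run_cell(index$ptr, pu, unname(haps$hap1$seq),
                        unname(haps$hap2$seq), n_pairs, strat$read_length,
                        strat$insert_mean, strat$insert_sd,
                        strat$error_rate,
                        as.integer(ceiling(0.04 * strat$read_length)),
                        as.numeric(mix_seed(cell_seed, 3)))
  called <- calls_from_pileup(pu, g, config$min_depth, config$min_alt_count,
                              config$min_alt_frac, config$hom_frac)
  ev <- evaluate_calls(truth, called, strata)
  ev$pairs_total <- stats[["pairs_total"]]
  ev$pairs_unique <- stats[["pairs_unique"]]
  ev
}

#' @export
print.mcr_grid_result <- function(x, ...) {
  cat("<mcr_grid_result> ", nrow(x$manifest), " dataset(s), ",
      nrow(x$report), " report row(s)\n", sep = "")
  invisible(x)
}
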