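#' Enumerate multi-hit seed windows
#'
#' Tiles seed windows of length \code{window} at \code{step}-bp intervals
#' over every chromosome and enumerates, for each N-free window, all exact
#' occurrences of its sequence genome-wide (on both strands by default, the
#' way a strand-blind aligner reports them). Only windows with at least two
#' occurrences are returned; each retained window's occurrence list includes
#' its own origin. There is no cap on occurrences per seed unless
#' \code{max_occ} is set as a performance guard.
#'
#' @param genome An \code{mcr_genome}.
#' @param window Seed window length in bp (default 300).
#' @param step Tiling step in bp (default 1; run merging requires 1).
#' @param strand_mode \code{"both"} (reverse-complement occurrences count)
#'   or \code{"forward"}.
#' @param max_occ Optional occurrence cap; seeds with more occurrences are
#'   dropped and counted in the \code{dropped_seeds} attribute.
#' @return A \code{seed_hits} data frame with one row per (seed window,
#'   occurrence): columns \code{seed_chrom}, \code{seed_start},
#'   \code{occ_chrom}, \code{occ_start} (1-based), \code{occ_strand}.
#'   Attributes: \code{window}, \code{step}, \code{strand_mode},
#'   \code{n_windows} (number of candidate window positions examined).
#' @export
enumerate_seed_hits <- function(genome, window = 300L, step = 1L,
                                strand_mode = c("both", "forward"),
                                max_occ = Inf) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(genome, "mcr_genome"))
  window <- as.integer(window)
  if (window < 2) stop("window must be >= 2")
  if (step < 1) stop("step must be >= 1")
  if (window > max(genome$lengths))
    stop("window exceeds the longest chromosome")
  raw <- cpp_seed_hits(unname(genome$seq), window, strand_mode == "both",
                       as.integer(step))
  chrn <- names(genome$seq)
  out <- data.frame(
    seed_chrom = chrn[raw$seed_chrom + 1L],
    seed_start = raw$seed_pos + 1L,
    occ_chrom = chrn[raw$occ_chrom + 1L],
    occ_start = raw$occ_pos + 1L,
    occ_strand = c("+", "-")[raw$occ_strand + 1L],
    stringsAsFactors = FALSE)
  if (is.finite(max_occ)) {
    key <- paste(out$seed_chrom, out$seed_start)
    nocc <- ave(seq_along(key), key, FUN = length)
    drop <- nocc > max_occ
    attr(out, "dropped_seeds") <- length(unique(key[drop]))
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "window") <- window
  attr(out, "step") <- as.integer(step)
  attr(out, "strand_mode") <- strand_mode
  attr(out, "n_windows") <-
    sum(ifelse(genome$lengths >= window,
               (genome$lengths - window) %/% as.integer(step) + 1L, 0L))
  attr(out, "chrom_names") <- chrn
  class(out) <- c("seed_hits", "data.frame")
  out
}

#' Merge consecutive co-occurring seeds into multi-copy sequence groups
#'
#' Implements the seed-merging rule: maximal runs of consecutive window
#' positions whose occurrence sets shift in lockstep (+1 for same-strand
#' occurrences, -1 for opposite-strand ones) are merged into a block of
#' length \code{run_length + window - 1}. A change in the occurrence set
#' interrupts continuity, so every resulting group shares a single MCS
#' across a constant locus set; blocks with identical locus extents
#' (discovered once per participating locus) are fused into one group.
#'
#' @param seed_hits A \code{seed_hits} table from [enumerate_seed_hits()]
#'   produced with \code{step = 1}.
#' @return An \code{mcs_groups} object: list with \code{groups} (data frame
#'   \code{group_id}, \code{length}, \code{n_loci}) and \code{loci} (data
#'   frame \code{group_id}, \code{chrom}, \code{start}, \code{end} 1-based
#'   inclusive, \code{strand} relative to the group's first locus).
#' @export
merge_seed_runs <- function(seed_hits) {
  if (!inherits(seed_hits, "seed_hits"))
    stop("expected a seed_hits table from enumerate_seed_hits()")
  if (attr(seed_hits, "step") != 1L)
    stop("run merging requires seed hits tiled at step = 1")
  w <- attr(seed_hits, "window")
  chrn <- attr(seed_hits, "chrom_names")
  raw <- cpp_merge_runs(match(seed_hits$seed_chrom, chrn) - 1L,
                        seed_hits$seed_start - 1L,
                        match(seed_hits$occ_chrom, chrn) - 1L,
                        seed_hits$occ_start - 1L,
                        match(seed_hits$occ_strand, c("+", "-")) - 1L,
                        w)
  groups <- data.frame(group_id = seq_along(raw$group_length),
                       length = raw$group_length,
                       n_loci = raw$group_nloci)
  loci <- data.frame(group_id = raw$locus_gid + 1L,
                     chrom = chrn[raw$locus_chrom + 1L],
                     start = raw$locus_start + 1L,
                     end = raw$locus_start + raw$group_length[raw$locus_gid + 1L],
                     strand = c("+", "-")[raw$locus_strand + 1L],
                     stringsAsFactors = FALSE)
  new_mcs_groups(groups, loci, w, attr(seed_hits, "strand_mode"), chrn)
}

new_mcs_groups <- function(groups, loci, window, strand_mode, chrom_names) {
  structure(list(groups = groups, loci = loci, window = window,
                 strand_mode = strand_mode, chrom_names = chrom_names),
            class = "mcs_groups")
}

#' @export
print.mcs_groups <- function(x, ...) {
  cat("<mcs_groups> ", nrow(x$groups), " group(s), ",
      nrow(x$loci), " loci; window ", x$window, " bp, strand mode '",
      x$strand_mode, "'\n", sep = "")
  if (nrow(x$groups) > 0) {
    cat("  MCS length range: ", min(x$groups$length), "-",
        max(x$groups$length), " bp; copy numbers ",
        min(x$groups$n_loci), "-", max(x$groups$n_loci), "\n", sep = "")
  }
  invisible(x)
}

#' Find multi-copy regions in a genome
#'
#' Convenience wrapper: [enumerate_seed_hits()] followed by
#' [merge_seed_runs()].
#'
#' @inheritParams enumerate_seed_hits
#' @return An \code{mcs_groups} object.
#' @examples
#' bg <- generate_background(c(chr1 = 20000, chr2 = 20000), seed = 7)
#' tb <- plant_duplications(bg, duplication_spec(400, 2, "inter"), seed = 7)
#' find_mcrs(tb$genome)
#' @export
find_mcrs <- function(genome, window = 300L, step = 1L,
                      strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  merge_seed_runs(enumerate_seed_hits(genome, window = window, step = step,
                                      strand_mode = strand_mode))
}

#' MCR loci of a group set as a GRanges
#'
#' @param x An \code{mcs_groups} object.
#' @return \code{GRanges} with \code{name} = group id and strand.
#' @export
mcr_loci <- function(x) {
  stopifnot(inherits(x, "mcs_groups"))
  if (nrow(x$loci) == 0)
    return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(x$loci$chrom,
                               IRanges::IRanges(x$loci$start, x$loci$end),
                               strand = x$loci$strand)
  S4Vectors::mcols(gr)$name <- sprintf("mcs%05d", x$loci$group_id)
  gr
}

#' Brute-force maximal exact repeat oracle
#'
#' Independent reference implementation of the finder's contract, used for
#' verification: every window is materialised as a string, occurrence sets
#' are obtained by direct string identity (and identity to reverse
#' complements), and runs are merged by grouping windows on a
#' shift-normalised occurrence-set key instead of the incremental lockstep
#' walk used by [merge_seed_runs()]. Quadratic-ish in memory; guarded to
#' genomes of at most 200 kb.
#'
#' @inheritParams enumerate_seed_hits
#' @return An \code{mcs_groups} object with the same canonical ordering as
#'   [merge_seed_runs()].
#' @export
brute_force_repeat_oracle <- function(genome, window = 300L,
                                      strand_mode = c("both", "forward")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(inherits(genome, "mcr_genome"))
  if (total_genome_length(genome) > 200000)
    stop("oracle size guard: genome exceeds 200 kb")
  w <- as.integer(window)
  if (w > max(genome$lengths)) stop("window exceeds the longest chromosome")

  both <- strand_mode == "both"
  chrn <- names(genome$seq)
  tab <- list()
  for (ci in seq_along(chrn)) {
    L <- genome$lengths[[ci]]
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    ws <- substring(genome$seq[[ci]], starts, starts + w - 1L)
    ok <- !grepl("N", ws, fixed = TRUE)
    df <- data.frame(chrom = ci, pos = starts[ok], fwd = ws[ok],
                     stringsAsFactors = FALSE)
    if (both) {
      # reverse complement of window [p, p+w) read off the whole-chromosome
      # reverse complement: rc(chrom)[L-p-w+2 .. L-p+1]
      rcs <- rc_string(genome$seq[[ci]])
      df$rc <- substring(rcs, L - (starts[ok] + w - 1L) + 1L,
                         L - starts[ok] + 1L)
    }
    tab[[ci]] <- df
  }
  tab <- do.call(rbind, tab)
  if (is.null(tab) || nrow(tab) == 0)
    return(new_mcs_groups(data.frame(group_id = integer(), length = integer(),
                                     n_loci = integer()),
                          data.frame(group_id = integer(), chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character(),
                                     stringsAsFactors = FALSE),
                          w, strand_mode, chrn))
  # occurrence sets by direct string identity over [fwd; rc]
  vals <- unique(tab$fwd)
  fid <- match(tab$fwd, vals)
  rid <- if (both) match(tab$rc, vals) else NULL

  occ_by_val <- split(seq_len(nrow(tab)), fid)
  rocc_by_val <- if (both) split(seq_len(nrow(tab)), rid) else list()

  key <- character(nrow(tab))
  nocc <- integer(nrow(tab))
  occs <- vector("list", nrow(tab))
  cnt_f <- tabulate(fid, nbins = length(vals))
  rhas <- logical(length(vals))
  if (both && any(!is.na(rid))) rhas[unique(rid[!is.na(rid)])] <- TRUE
  cand <- which(cnt_f[fid] >= 2L | (both & rhas[fid]))
  for (i in cand) {
    f <- occ_by_val[[as.character(fid[i])]]
    r <- if (both) rocc_by_val[[as.character(fid[i])]] else NULL
    # r: windows whose reverse complement equals this window
    if (!is.null(r)) r <- r[!(r == i)]
    n <- length(f) + length(r)
    nocc[i] <- n
    if (n < 2) next
    chrom <- c(tab$chrom[f], tab$chrom[r])
    pos <- c(tab$pos[f], tab$pos[r])
    strand <- rep(c("+", "-"), c(length(f), length(r)))
    d <- pos + ifelse(strand == "+", -1L, 1L) * tab$pos[i]
    o <- order(chrom, strand, d)
    occs[[i]] <- list(chrom = chrom[o], pos = pos[o], strand = strand[o])
    key[i] <- paste(chrom[o], strand[o], d[o], sep = ":", collapse = ";")
  }

  multi <- which(nocc >= 2)
  if (length(multi) == 0)
    return(new_mcs_groups(data.frame(group_id = integer(), length = integer(),
                                     n_loci = integer()),
                          data.frame(group_id = integer(), chrom = character(),
                                     start = integer(), end = integer(),
                                     strand = character(),
                                     stringsAsFactors = FALSE),
                          w, strand_mode, chrn))

  mt <- tab[multi, c("chrom", "pos")]
  mt$key <- key[multi]
  mt$idx <- multi
  o <- order(mt$chrom, mt$key, mt$pos)
  mt <- mt[o, , drop = FALSE]
  newrun <- c(TRUE, !(mt$chrom[-1] == mt$chrom[-nrow(mt)] &
                        mt$key[-1] == mt$key[-nrow(mt)] &
                        mt$pos[-1] == mt$pos[-nrow(mt)] + 1L))
  runid <- cumsum(newrun)

  sigs <- character(0)
  glen <- integer(0); gnl <- integer(0)
  loci_list <- list()
  for (rid2 in unique(runid)) {
    rows <- which(runid == rid2)
    p1 <- mt$pos[rows[1]]; p2 <- mt$pos[rows[length(rows)]]
    r <- p2 - p1 + 1L
    len <- r + w - 1L
    oc <- occs[[mt$idx[rows[1]]]]
    start <- as.integer(ifelse(oc$strand == "+", oc$pos, oc$pos - r + 1L))
    lo <- data.frame(chrom = chrn[oc$chrom], start = start,
                     end = start + len - 1L, strand = oc$strand,
                     stringsAsFactors = FALSE)
    oo <- order(lo$chrom, lo$start, lo$strand)
    lo <- lo[oo, , drop = FALSE]
    if (lo$strand[1] == "-")
      lo$strand <- c("+" = "-", "-" = "+")[lo$strand]
    sig <- paste(len, paste(lo$chrom, lo$start, lo$strand, sep = ",",
                            collapse = "|"), sep = "|")
    if (sig %in% sigs) next
    sigs <- c(sigs, sig)
    glen <- c(glen, len); gnl <- c(gnl, nrow(lo))
    lo$group_id <- length(glen)
    loci_list[[length(loci_list) + 1L]] <- lo
  }
  groups <- data.frame(group_id = seq_along(glen), length = glen,
                       n_loci = gnl)
  loci <- do.call(rbind, loci_list)[, c("group_id", "chrom", "start", "end",
                                        "strand")]
  rownames(loci) <- NULL
  new_mcs_groups(groups, loci, w, strand_mode, chrn)
}

#' Summary statistics of a group set
#'
#' Genome coverage fraction (union of all loci over total genome length),
#' per-chromosome MCR percentage, MCS length histogram (50-bp bins by
#' default), copy-number histogram and intra-/inter-chromosome
#' classification (a group is intra-chromosomal iff all its loci share one
#' chromosome).
#'
#' @param x An \code{mcs_groups} object.
#' @param genome The \code{mcr_genome} the groups were found in.
#' @param length_bin Histogram bin width for MCS lengths, bp.
#' @return An \code{mcr_summary} list.
#' @export
summarize_mcrs <- function(x, genome, length_bin = 50L) {
  stopifnot(inherits(x, "mcs_groups"), inherits(genome, "mcr_genome"))
  if (nrow(x$groups) == 0) {
    return(structure(list(
      coverage = 0, per_chrom = setNames(rep(0, length(genome$seq)),
                                         names(genome$seq)),
      length_hist = table(factor(character())),
      copy_hist = table(factor(integer())),
      classification = character(0), n_groups = 0L, n_loci = 0L),
      class = "mcr_summary"))
  }
  gr <- unstrand_drop(mcr_loci(x))
  validate_intervals(gr, genome)
  u <- GenomicRanges::reduce(gr)
  coverage <- sum(as.numeric(GenomicRanges::width(u))) /
    total_genome_length(genome)
  per_chrom <- vapply(names(genome$seq), function(cn) {
    ui <- u[as.character(GenomicRanges::seqnames(u)) == cn]
    sum(as.numeric(GenomicRanges::width(ui))) / genome$lengths[[cn]]
  }, numeric(1))
  brk <- seq(x$window, max(x$groups$length) + length_bin, by = length_bin)
  length_hist <- table(cut(x$groups$length, breaks = brk, right = FALSE,
                           include.lowest = TRUE))
  copy_hist <- table(x$groups$n_loci)
  classification <- vapply(split(x$loci$chrom, x$loci$group_id),
                           function(ch) if (length(unique(ch)) == 1L)
                             "intra" else "inter", character(1))
  structure(list(coverage = coverage, per_chrom = per_chrom,
                 length_hist = length_hist, copy_hist = copy_hist,
                 classification = classification,
                 n_groups = nrow(x$groups), n_loci = nrow(x$loci)),
            class = "mcr_summary")
}

#' @export
print.mcr_summary <- function(x, ...) {
  cat("<mcr_summary> ", x$n_groups, " group(s), ", x$n_loci, " loci\n",
      "  genome coverage: ", sprintf("%.4f%%", 100 * x$coverage), "\n",
      sep = "")
  if (x$n_groups > 0) {
    cls <- table(x$classification)
    cat("  intra/inter-chromosome groups: ",
        if ("intra" %in% names(cls)) cls[["intra"]] else 0L, "/",
        if ("inter" %in% names(cls)) cls[["inter"]] else 0L, "\n", sep = "")
  }
  invisible(x)
}
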