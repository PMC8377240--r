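#' Define MCR and matched flanking strata
#'
#' Every MCR interval contributes flanking sequence of the same total
#' length, split half upstream and half downstream. Flanks are clipped at
#' chromosome ends and trimmed so they never overlap the MCR union or a
#' previously allocated flank; sequence lost to clipping on one side is
#' reallocated to the other side when space allows, so the total flank
#' length equals the total MCR length whenever no hard clipping occurred.
#'
#' @param mcr \code{GRanges} of MCR intervals (overlaps are unioned first).
#' @param genome An \code{mcr_genome}.
#' @return Named list of \code{GRanges}: \code{MCR} (the union) and
#'   \code{flank}.
#' @export
define_strata <- function(mcr, genome) {
  validate_intervals(mcr, genome)
  u <- GenomicRanges::reduce(unstrand_drop(mcr))
  u <- GenomicRanges::sort(u)
  blocked <- u  # MCRs plus already-allocated flanks
  flanks <- GenomicRanges::GRanges()

  # largest prefix [edge, edge +/- want) of free space, contiguous from edge
  grab <- function(chrom, from, want, dir) {
    if (want <= 0) return(NULL)
    L <- genome$lengths[[chrom]]
    if (dir > 0) { lo <- from; hi <- min(from + want - 1L, L) }
    else         { hi <- from; lo <- max(from - want + 1L, 1L) }
    if (lo > hi) return(NULL)
    cand <- GenomicRanges::GRanges(chrom, IRanges::IRanges(lo, hi))
    free <- GenomicRanges::setdiff(cand, blocked)
    if (length(free) == 0) return(NULL)
    # keep only the piece touching the MCR edge
    if (dir > 0) {
      free <- free[GenomicRanges::start(free) == lo]
    } else {
      free <- free[GenomicRanges::end(free) == hi]
    }
    if (length(free) == 0) return(NULL)
    free[1]
  }

  for (i in seq_along(u)) {
    chrom <- as.character(GenomicRanges::seqnames(u[i]))
    s <- GenomicRanges::start(u[i]); e <- GenomicRanges::end(u[i])
    L <- e - s + 1L
    want_up <- as.integer(ceiling(L / 2)); want_dn <- L - want_up
    up <- grab(chrom, s - 1L, want_up, -1L)
    got_up <- if (is.null(up)) 0L else GenomicRanges::width(up)
    # shortfall upstream is reallocated downstream, and vice versa
    dn <- grab(chrom, e + 1L, want_dn + (want_up - got_up), 1L)
    got_dn <- if (is.null(dn)) 0L else GenomicRanges::width(dn)
    deficit <- L - got_up - got_dn
    if (deficit > 0L && got_up > 0L) {
      extra <- grab(chrom, GenomicRanges::start(up) - 1L, deficit, -1L)
      if (!is.null(extra)) up <- GenomicRanges::reduce(c(up, extra))
    }
    add <- GenomicRanges::GRanges()
    if (!is.null(up)) add <- c(add, up)
    if (!is.null(dn)) add <- c(add, dn)
    if (length(add) > 0) {
      flanks <- c(flanks, add)
      blocked <- GenomicRanges::reduce(c(blocked, add))
    } else if (genome$lengths[[chrom]] == L) {
      warning("MCR occupies all of ", chrom, "; no flank possible")
    }
  }
  flanks <- GenomicRanges::sort(GenomicRanges::reduce(flanks))
  list(MCR = u, flank = flanks)
}

#' Plant SNVs into strata at a fixed per-base rate
#'
#' Each base of each stratum is independently mutated with probability
#' \code{rate} (the headline design uses one SNV per kb). The alternate
#' base is drawn uniformly from the three non-reference bases; the genotype
#' is heterozygous with probability \code{het_fraction}, else homozygous.
#'
#' @param strata Named list of \code{GRanges} (from [define_strata()]), or a
#'   single \code{GRanges} (stratum named \code{"all"}).
#' @param genome An \code{mcr_genome}.
#' @param rate Per-base SNV probability in \code{(0, 0.1]} (default 0.001).
#' @param het_fraction Probability a variant is heterozygous (default 0.5).
#' @param seed Integer seed.
#' @return Variant data frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{genotype}, \code{stratum}.
#' @export
plant_snvs <- function(strata, genome, rate = 0.001, het_fraction = 0.5,
                       seed = 1L) {
  if (inherits(strata, "GRanges")) strata <- list(all = strata)
  if (rate <= 0 || rate > 0.1) stop("rate must be in (0, 0.1]")
  if (het_fraction < 0 || het_fraction > 1)
    stop("het_fraction must be in [0, 1]")
  if (all(vapply(strata, length, integer(1)) == 0))
    warning("empty strata: no SNVs planted")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    out <- list()
    for (nm in names(strata)) {
      gr <- GenomicRanges::reduce(unstrand_drop(strata[[nm]]))
      if (length(gr) == 0) next
      validate_intervals(gr, genome)
      chrom <- rep(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::width(gr))
      pos <- unlist(lapply(seq_along(gr), function(i)
        seq.int(GenomicRanges::start(gr[i]), GenomicRanges::end(gr[i]))))
      hit <- runif(length(pos)) < rate
      if (!any(hit)) next
      chrom <- chrom[hit]; pos <- pos[hit]
      ref <- substring(genome$seq[chrom], pos, pos)
      alt <- vapply(ref, function(r)
        sample(setdiff(bases, r), 1L), character(1), USE.NAMES = FALSE)
      gt <- ifelse(runif(length(pos)) < het_fraction, "het", "hom")
      out[[nm]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                              alt = alt, genotype = gt, stratum = nm,
                              stringsAsFactors = FALSE)
    }
    res <- if (length(out)) do.call(rbind, out) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), genotype = character(),
                 stratum = character(), stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
  })
}

#' Build a diploid pair of haplotypes from truth variants
#'
#' Homozygous variants are applied to both haplotypes; heterozygous ones to
#' exactly one, chosen uniformly and recorded. SNVs only, so haplotype
#' lengths equal the reference.
#'
#' @param genome An \code{mcr_genome}.
#' @param variants Truth variant data frame (one variant per position).
#' @param seed Integer seed for the haplotype assignment of het variants.
#' @return List with \code{hap1}, \code{hap2} (each \code{mcr_genome}) and
#'   \code{phase} (the variant table plus a \code{haplotype} column: 0 =
#'   both, 1 or 2 = carrier of a het variant).
#' @export
build_haplotypes <- function(genome, variants, seed = 1L) {
  validate_variants(variants, genome)
  if (anyDuplicated(paste(variants$chrom, variants$pos)))
    stop("conflicting variants: one variant per position required")
  if (nrow(variants) > 0 &&
      any(substring(genome$seq[as.character(variants$chrom)], variants$pos,
                    variants$pos) != variants$ref))
    stop("variant ref base does not match the genome")
  h1 <- genome$seq; h2 <- genome$seq
  phase <- variants
  phase$haplotype <- integer(nrow(variants))
  with_seed(seed, {
    if (nrow(variants) > 0) {
      het <- !is.na(variants$genotype) & variants$genotype == "het"
      phase$haplotype[het] <- 1L + (runif(sum(het)) < 0.5)
      for (cn in unique(as.character(variants$chrom))) {
        idx <- which(variants$chrom == cn)
        to1 <- idx[phase$haplotype[idx] %in% c(0L, 1L)]
        to2 <- idx[phase$haplotype[idx] %in% c(0L, 2L)]
        if (length(to1))
          h1[[cn]] <- replace_bases(h1[[cn]], variants$pos[to1],
                                    variants$alt[to1])
        if (length(to2))
          h2[[cn]] <- replace_bases(h2[[cn]], variants$pos[to2],
                                    variants$alt[to2])
      }
    }
  })
  list(hap1 = genome(h1), hap2 = genome(h2), phase = phase)
}

replace_bases <- function(seq, pos, letters) {
  as.character(Biostrings::replaceLetterAt(
    Biostrings::DNAString(seq), as.integer(pos),
    paste(letters, collapse = "")))
}

#' Sequencing strategy descriptor
#'
#' @param read_length Read length in bp (the study grid uses 75 and 150).
#' @param depth Target mean sequencing depth (fold coverage).
#' @param error_rate Per-base sequencing error probability (default 0.01).
#' @param insert_mean,insert_sd Fragment-size distribution in bp (default
#'   400 +/- 50, the midpoint of the 300-500 bp range typical of paired-end
#'   libraries).
#' @return A \code{sim_strategy}.
#' @export
sim_strategy <- function(read_length = 150L, depth = 30, error_rate = 0.01,
                         insert_mean = 400, insert_sd = 50) {
  if (depth <= 0) stop("depth must be positive")
  if (insert_mean < 2 * read_length)
    stop("insert mean must be at least twice the read length")
  if (error_rate < 0 || error_rate >= 1)
    stop("error_rate must be in [0, 1)")
  structure(list(read_length = as.integer(read_length), depth = depth,
                 error_rate = error_rate, insert_mean = insert_mean,
                 insert_sd = insert_sd),
            class = "sim_strategy")
}

#' @export
print.sim_strategy <- function(x, ...) {
  cat(sprintf("<sim_strategy> PE%d at %gx, error %g, insert %g +/- %g bp\n",
              x$read_length, x$depth, x$error_rate, x$insert_mean,
              x$insert_sd))
  invisible(x)
}

strategy_label <- function(x) sprintf("PE%d_%gx", x$read_length, x$depth)

#' Simulate paired-end reads from a diploid genome
#'
#' wgsim-style simulator: the number of pairs is
#' \code{round(depth * genome_length / (2 * read_length))}; fragments start
#' uniformly, fragment length is normal (truncated to at least twice the
#' read length), the haplotype is chosen uniformly per fragment, and each
#' sequenced base is flipped to a uniformly chosen different base with
#' probability \code{error_rate}. Mate 2 is the reverse complement of the
#' far end of the fragment; which physical mate is the forward one is
#' randomised per pair. Chromosomes shorter than the maximum fragment
#' length (insert mean + 4 sd) are excluded with a warning.
#'
#' @param haplotypes Result of [build_haplotypes()] (or an
#'   \code{mcr_genome}, treated as a homozygous diploid).
#' @param strategy A \code{sim_strategy}.
#' @param seed Integer seed.
#' @return A \code{read_pairs} list: \code{read1}, \code{read2}, \code{id},
#'   and a \code{truth} data frame (chrom, fragment start 1-based, fragment
#'   length, haplotype, flip).
#' @export
simulate_read_pairs <- function(haplotypes, strategy, seed = 1L) {
  stopifnot(inherits(strategy, "sim_strategy"))
  if (inherits(haplotypes, "mcr_genome"))
    haplotypes <- list(hap1 = haplotypes, hap2 = haplotypes)
  h1 <- haplotypes$hap1; h2 <- haplotypes$hap2
  stopifnot(inherits(h1, "mcr_genome"), inherits(h2, "mcr_genome"))
  if (!identical(h1$lengths, h2$lengths))
    stop("haplotypes must have identical chromosome lengths")
  max_frag <- strategy$insert_mean + 4 * strategy$insert_sd
  keep <- h1$lengths >= max_frag
  if (!all(keep)) {
    warning("excluding chromosome(s) shorter than the maximum fragment: ",
            paste(names(h1$lengths)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no chromosome long enough to simulate from")
  chrn <- names(h1$seq)[keep]
  glen <- sum(as.numeric(h1$lengths[keep]))
  n_pairs <- as.integer(round(strategy$depth * glen /
                                (2 * strategy$read_length)))
  raw <- cpp_simulate_pairs(unname(h1$seq[keep]), unname(h2$seq[keep]),
                            n_pairs, strategy$read_length,
                            strategy$insert_mean, strategy$insert_sd,
                            strategy$error_rate, as.numeric(seed))
  structure(list(
    read1 = raw$read1, read2 = raw$read2,
    id = if (n_pairs > 0) sprintf("sim%07d", seq_len(n_pairs)) else character(0),
    truth = data.frame(chrom = chrn[raw$chrom + 1L],
                       frag_start = raw$frag_start + 1L,
                       frag_len = raw$frag_len, haplotype = raw$haplotype,
                       flip = raw$flip, stringsAsFactors = FALSE),
    strategy = strategy, chrom_names = chrn),
    class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("<read_pairs> ", length(x$read1), " pair(s), ",
      strategy_label(x$strategy), "\n", sep = "")
  invisible(x)
}
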