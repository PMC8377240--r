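#' Build a k-mer position index over a genome
#'
#' Every N-free k-mer of the forward strand maps to its full genome-wide
#' position list. Reads are looked up in both orientations at query time
#' (forward k-mers of the read and of its reverse complement), so the index
#' itself is single-stranded; this convention keeps every k-mer's position
#' list complete and uncapped.
#'
#' @param genome An \code{mcr_genome}.
#' @param k Anchor k-mer length; odd, between 15 and 63 (default 31).
#' @return A \code{read_index} wrapping the native index.
#' @export
build_index <- function(genome, k = 31L) {
  stopifnot(inherits(genome, "mcr_genome"))
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 15L || k > 63L) stop("k must be between 15 and 63")
  ptr <- cpp_build_index(unname(genome$seq), k)
  structure(list(ptr = ptr, k = k, chrom_names = names(genome$seq),
                 lengths = genome$lengths),
            class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat("<read_index> k =", x$k, "over", length(x$chrom_names),
      "sequence(s)\n")
  invisible(x)
}

#' Look up a k-mer's positions in an index
#'
#' @param index A \code{read_index}.
#' @param kmer Character k-mer (forward strand).
#' @return Data frame of 1-based positions (\code{chrom}, \code{start}).
#' @export
index_lookup <- function(index, kmer) {
  stopifnot(inherits(index, "read_index"))
  m <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(chrom = index$chrom_names[m[, 1] + 1L], start = m[, 2] + 1L,
             stringsAsFactors = FALSE)
}

#' Map read pairs with a strict unique-mapping filter
#'
#' Seed-and-verify mapping: candidate placements are gathered from k-mer
#' anchors of both mates in both orientations, concordant placements
#' (forward/reverse orientation, fragment length within mean +/- 4 sd) are
#' scored by total mismatches, and the reported alignment is the
#' minimal-mismatch concordant placement. The uniqueness flag is a strict
#' co-optimality test: it is \code{TRUE} only when exactly one placement
#' attains the minimum score. Pairs that are non-unique or unplaceable are
#' flagged for discard; there are no mapping-quality heuristics.
#'
#' @param pairs A \code{read_pairs} object (or list with \code{read1},
#'   \code{read2}).
#' @param index A \code{read_index} built on the target genome.
#' @param max_mismatch Per-read mismatch tolerance; default
#'   \code{ceiling(0.04 * read length)}.
#' @param insert_mean,insert_sd Expected fragment-size distribution used
#'   for the concordance window (defaults taken from the pairs' strategy
#'   when available, else 400 +/- 50).
#' @return An \code{alignments} data frame: \code{pair}, \code{mapped},
#'   \code{unique}, \code{chrom}, \code{pos1}, \code{strand1}, \code{pos2},
#'   \code{strand2} (1-based alignment starts of each mate), total
#'   \code{mismatches} and \code{n_best} co-optimal placements.
#' @export
map_read_pairs <- function(pairs, index, max_mismatch = NULL,
                           insert_mean = NULL, insert_sd = NULL) {
  stopifnot(inherits(index, "read_index"))
  r1 <- pairs$read1; r2 <- pairs$read2
  if (length(r1) != length(r2)) stop("mate vectors differ in length")
  if (is.null(insert_mean))
    insert_mean <- if (!is.null(pairs$strategy)) pairs$strategy$insert_mean
      else 400
  if (is.null(insert_sd))
    insert_sd <- if (!is.null(pairs$strategy)) pairs$strategy$insert_sd
      else 50
  if (is.null(max_mismatch)) {
    rl <- if (length(r1)) max(nchar(r1)) else 0L
    max_mismatch <- ceiling(0.04 * rl)
  }
  raw <- cpp_map_pairs(index$ptr, r1, r2, as.integer(max_mismatch),
                       insert_mean, insert_sd)
  out <- data.frame(
    pair = seq_along(r1),
    mapped = raw$mapped, unique = raw$unique,
    chrom = ifelse(is.na(raw$chrom), NA_character_,
                   index$chrom_names[raw$chrom + 1L]),
    pos1 = raw$pos1 + 1L, strand1 = as.character(raw$strand1),
    pos2 = raw$pos2 + 1L, strand2 = as.character(raw$strand2),
    mismatches = raw$mismatches, n_best = raw$n_best,
    stringsAsFactors = FALSE)
  attr(out, "max_mismatch") <- max_mismatch
  class(out) <- c("alignments", "data.frame")
  out
}

#' Mapping statistics
#' @param alignments An \code{alignments} data frame.
#' @return One-row data frame: pairs total, uniquely mapped, discarded.
#' @export
mapping_stats <- function(alignments) {
  data.frame(pairs_total = nrow(alignments),
             pairs_unique = sum(alignments$unique),
             pairs_discarded = sum(!alignments$unique))
}

# accumulate a pileup from uniquely mapped pairs; internal
pileup_from_alignments <- function(alignments, pairs, genome) {
  pu <- cpp_pileup_new(unname(genome$seq))
  keep <- which(alignments$unique)
  if (length(keep) > 0) {
    cidx <- match(alignments$chrom[keep], names(genome$seq)) - 1L
    cpp_pileup_add(pu, cidx, alignments$pos1[keep] - 1L,
                   alignments$strand1[keep], pairs$read1[alignments$pair[keep]])
    cpp_pileup_add(pu, cidx, alignments$pos2[keep] - 1L,
                   alignments$strand2[keep], pairs$read2[alignments$pair[keep]])
  }
  pu
}

#' Per-site pileup counts from uniquely mapped pairs
#'
#' @param alignments An \code{alignments} data frame.
#' @param pairs The \code{read_pairs} the alignments refer to.
#' @param genome The target \code{mcr_genome}.
#' @param min_depth Only sites with at least this depth are returned.
#' @return Data frame: \code{chrom}, \code{pos} (1-based), \code{ref},
#'   counts \code{A}, \code{C}, \code{G}, \code{T} and \code{depth}.
#' @export
pileup_counts <- function(alignments, pairs, genome, min_depth = 1L) {
  pu <- pileup_from_alignments(alignments, pairs, genome)
  df <- cpp_pileup_sites(pu, as.integer(min_depth))
  df$chrom <- names(genome$seq)[df$chrom + 1L]
  df$pos <- df$pos + 1L
  df$depth <- df$A + df$C + df$G + df$T
  df
}

#' Pileup SNV caller over uniquely mapped reads
#'
#' Per site, the alternate allele is the most frequent non-reference base
#' (ties broken lexicographically). A variant is called iff depth >=
#' \code{min_depth}, alternate count >= \code{min_alt_count} and alternate
#' fraction >= \code{min_alt_frac}; the genotype is homozygous iff the
#' alternate fraction reaches \code{hom_frac}, else heterozygous.
#'
#' @inheritParams pileup_counts
#' @param min_depth Minimum depth at the site (default 4).
#' @param min_alt_count Minimum alternate-allele read count (default 2).
#' @param min_alt_frac Minimum alternate-allele fraction (default 0.2).
#' @param hom_frac Alternate fraction at or above which a call is
#'   homozygous (default 0.8).
#' @return Variant data frame: \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{genotype}, \code{depth}, \code{alt_count},
#'   \code{alt_frac}.
#' @export
pileup_and_call <- function(alignments, pairs, genome, min_depth = 4L,
                            min_alt_count = 2L, min_alt_frac = 0.2,
                            hom_frac = 0.8) {
  pu <- pileup_from_alignments(alignments, pairs, genome)
  calls_from_pileup(pu, genome, min_depth, min_alt_count, min_alt_frac,
                    hom_frac)
}

# threshold scan over an accumulated native pileup; internal
calls_from_pileup <- function(pu, genome, min_depth, min_alt_count,
                              min_alt_frac, hom_frac) {
  df <- cpp_pileup_call(pu, as.integer(min_depth), as.integer(min_alt_count),
                        min_alt_frac, hom_frac)
  data.frame(chrom = names(genome$seq)[df$chrom + 1L], pos = df$pos + 1L,
             ref = df$ref, alt = df$alt,
             genotype = ifelse(df$hom == 1L, "hom", "het"),
             depth = df$depth, alt_count = df$alt_count,
             alt_frac = df$alt_frac, stringsAsFactors = FALSE)
}
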