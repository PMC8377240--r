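#' Generate an i.i.d. background genome
#'
#' Produces random background sequence with a given GC content. The
#' background is intentionally free of repeat structure so that planted
#' duplications (see [plant_duplications()]) are, with overwhelming
#' probability, the only exact repeats at or above the seed window length:
#' the chance that two random 300-mers collide anywhere in a megabase-scale
#' genome is astronomically small.
#'
#' @param chrom_lengths Named (or unnamed, then \code{chr1..chrN}) integer
#'   vector of chromosome lengths in bp; each must be at least 1000.
#' @param gc GC content in (0, 1); bases are i.i.d. with
#'   \code{P(G) + P(C) = gc}.
#' @param seed Integer seed; the same seed reproduces the genome exactly.
#' @return An \code{mcr_genome}.
#' @export
generate_background <- function(chrom_lengths, gc = 0.41, seed = 1L) {
  if (any(chrom_lengths < 1000))
    stop("chromosome lengths must be at least 1 kb")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chrom_lengths))
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    seqs <- vapply(as.integer(chrom_lengths), function(L) {
      paste(sample(names(prob), L, replace = TRUE, prob = prob),
            collapse = "")
    }, character(1))
    genome(setNames(seqs, nm))
  })
}

#' Describe a duplication to plant
#'
#' @param length Segment length in bp (>= 1).
#' @param copies Total copy number (>= 2).
#' @param mode Placement of the extra copies: \code{"inter"} spreads copies
#'   across chromosomes, \code{"intra"} keeps them on the source chromosome,
#'   \code{"tandem"} places all copies adjacent in one block.
#' @param strands Strand of each extra copy (\code{length copies - 1}),
#'   default all \code{"+"}; \code{"-"} plants the reverse complement.
#' @param divergence Per-copy substitution rate in \code{[0, 1)}; extra
#'   copies receive \code{Binomial(length, divergence)} random substitutions.
#'   Non-zero divergence breaks exactness, so such copies must not be
#'   recovered as full-length multi-copy sequences.
#' @return A \code{duplication_spec}.
#' @export
duplication_spec <- function(length, copies = 2L,
                             mode = c("inter", "intra", "tandem"),
                             strands = NULL, divergence = 0) {
  mode <- match.arg(mode)
  if (length < 1) stop("length must be >= 1")
  if (copies < 2) stop("copy number must be >= 2")
  if (divergence < 0 || divergence >= 1) stop("divergence must be in [0, 1)")
  if (is.null(strands)) strands <- rep("+", copies - 1)
  if (base::length(strands) != copies - 1)
    stop("strands must have one entry per extra copy")
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' or '-'")
  if (mode == "tandem" && any(strands == "-"))
    stop("tandem mode supports '+' copies only")
  structure(list(length = as.integer(length), copies = as.integer(copies),
                 mode = mode, strands = strands, divergence = divergence),
            class = "duplication_spec")
}

rc_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Plant exact (or divergent) duplications into a background genome
#'
#' For each spec, a source segment of background is chosen and copied into
#' \code{copies - 1} destination loci by overwriting background, honouring a
#' minimum unique margin around every planted segment so that no two planted
#' segments come closer than \code{margin} bp. The bases immediately
#' flanking the copies of a group are then adjusted so that no two copies
#' share the same extension letter on either side ("junction
#' distinctness"): without this, flanking background matches by chance with
#' probability 1/4 per side and the maximal exact repeat is longer than the
#' planted segment. With a 4-letter alphabet this adjustment is guaranteed
#' for up to 4 copies per group (and for the outer junctions of tandem
#' blocks); beyond that, chance extensions of copy subsets can occur.
#'
#' @param genome An \code{mcr_genome} (background).
#' @param specs A \code{duplication_spec} or list of them.
#' @param seed Integer seed.
#' @param margin Minimum background distance (bp) between planted segments
#'   and to chromosome ends (default 1000).
#' @param max_retries Placement attempts per segment before giving up.
#' @return An \code{mcr_truth_build}: list with \code{genome} (modified),
#'   \code{truth} (GRanges of every planted copy, \code{name} = group
#'   label), \code{unique_regions} (complement of the truth union),
#'   \code{substitutions} (data frame of divergence edits) and \code{specs}.
#' @export
plant_duplications <- function(genome, specs, seed = 1L, margin = 1000L,
                               max_retries = 1000L) {
  if (inherits(specs, "duplication_spec")) specs <- list(specs)
  if (!all(vapply(specs, inherits, logical(1), "duplication_spec")))
    stop("specs must be duplication_spec objects")
  g <- genome
  total_plant <- sum(vapply(specs, function(s) as.numeric(s$length) * s$copies,
                            numeric(1)))
  if (total_plant > 0.5 * total_genome_length(g))
    stop("total planted length exceeds 50% of the genome")

  chroms <- names(g$seq)
  occupied <- data.frame(chrom = character(), start = integer(),
                         end = integer(), stringsAsFactors = FALSE)
  is_free <- function(chrom, start, end) {
    L <- g$lengths[[chrom]]
    if (start - margin < 1 || end + margin > L) return(FALSE)
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    if (nrow(occ) == 0) return(TRUE)
    !any(occ$start <= end + margin & occ$end >= start - margin)
  }
  place <- function(chrom, len) {
    L <- g$lengths[[chrom]]
    for (i in seq_len(max_retries)) {
      lo <- 1L + margin
      hi <- L - len + 1L - margin
      if (hi < lo) break
      s <- lo + floor(runif(1) * (hi - lo + 1))
      if (is_free(chrom, s, s + len - 1L)) return(as.integer(s))
    }
    stop("placement error: could not place a ", len,
         " bp segment on ", chrom, " within margin constraints")
  }

  truth <- list()
  subs <- list()

  with_seed(seed, {
    for (si in seq_along(specs)) {
      sp <- specs[[si]]
      label <- sprintf("dup%02d", si)
      len <- sp$length
      strands <- c("+", sp$strands)

      if (sp$mode == "tandem") {
        block <- len * sp$copies
        c0 <- chroms[[1L + floor(runif(1) * length(chroms))]]
        bs <- place(c0, block)
        starts <- bs + len * (seq_len(sp$copies) - 1L)
        copy_chrom <- rep(c0, sp$copies)
        occupied <- rbind(occupied, data.frame(chrom = c0, start = bs,
          end = bs + block - 1L, stringsAsFactors = FALSE))
      } else {
        c0 <- chroms[[1L + floor(runif(1) * length(chroms))]]
        s0 <- place(c0, len)
        occupied <- rbind(occupied, data.frame(chrom = c0, start = s0,
          end = s0 + len - 1L, stringsAsFactors = FALSE))
        copy_chrom <- c0
        starts <- s0
        for (ci in 2:sp$copies) {
          cc <- if (sp$mode == "inter" && length(chroms) > 1) {
            i0 <- match(c0, chroms)
            chroms[[((i0 - 1L + ci - 1L) %% length(chroms)) + 1L]]
          } else c0
          sc <- place(cc, len)
          occupied <- rbind(occupied, data.frame(chrom = cc, start = sc,
            end = sc + len - 1L, stringsAsFactors = FALSE))
          copy_chrom <- c(copy_chrom, cc)
          starts <- c(starts, sc)
        }
      }

      src <- substr(g$seq[[copy_chrom[1]]], starts[1], starts[1] + len - 1L)
      for (ci in seq_len(sp$copies)) {
        content <- if (ci == 1) src else
          if (strands[ci] == "+") src else rc_string(src)
        if (ci > 1 && sp$divergence > 0) {
          nsub <- rbinom(1, len, sp$divergence)
          if (nsub > 0) {
            at <- sort(sample.int(len, nsub))
            ch <- strsplit(content, "")[[1]]
            for (p in at) {
              old <- ch[p]
              ch[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
              subs[[length(subs) + 1L]] <- data.frame(
                group = label, copy = ci, chrom = copy_chrom[ci],
                pos = starts[ci] + p - 1L, from = old, to = ch[p],
                stringsAsFactors = FALSE)
            }
            content <- paste(ch, collapse = "")
          }
        }
        if (ci > 1)
          substr(g$seq[[copy_chrom[ci]]], starts[ci],
                 starts[ci] + len - 1L) <- content
        truth[[length(truth) + 1L]] <- data.frame(
          chrom = copy_chrom[ci], start = starts[ci],
          end = starts[ci] + len - 1L, name = label,
          strand = strands[ci], copy = ci, stringsAsFactors = FALSE)
      }

      g <- enforce_junctions(g, copy_chrom, starts, len, strands, occupied)
    }
  })

  truth_df <- do.call(rbind, truth)
  truth_gr <- GenomicRanges::GRanges(
    truth_df$chrom, IRanges::IRanges(truth_df$start, truth_df$end),
    strand = truth_df$strand)
  S4Vectors::mcols(truth_gr)$name <- truth_df$name
  S4Vectors::mcols(truth_gr)$copy <- truth_df$copy

  gaps <- GenomicRanges::setdiff(
    GenomicRanges::GRanges(names(g$seq),
                           IRanges::IRanges(1L, unname(g$lengths))),
    unstrand_drop(truth_gr))

  structure(list(genome = genome(g$seq), truth = truth_gr,
                 unique_regions = gaps,
                 substitutions = if (length(subs)) do.call(rbind, subs) else
                   data.frame(group = character(), copy = integer(),
                              chrom = character(), pos = integer(),
                              from = character(), to = character(),
                              stringsAsFactors = FALSE),
                 specs = specs),
            class = "mcr_truth_build")
}

#' @export
print.mcr_truth_build <- function(x, ...) {
  cat("<mcr_truth_build> ", length(x$specs), " duplication group(s), ",
      length(x$truth), " planted copies\n", sep = "")
  print(x$genome)
  invisible(x)
}

# Make the "extension letters" of a duplication group pairwise distinct on
# each side, so the planted segment is the maximal exact repeat. For a '+'
# copy [s, e] the left extension letter is base(s-1) and the right one is
# base(e+1); for a '-' copy they are comp(base(e+1)) and comp(base(s-1)).
# Positions inside other planted segments (tandem interiors) are not edited.
enforce_junctions <- function(g, copy_chrom, starts, len, strands, occupied) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ends <- starts + len - 1L
  in_planted <- function(chrom, pos) {
    occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
    any(occ$start <= pos & occ$end >= pos)
  }
  for (side in c("left", "right")) {
    slots <- lapply(seq_along(starts), function(ci) {
      plus <- strands[ci] == "+"
      if (xor(side == "left", !plus)) {
        list(chrom = copy_chrom[ci], pos = starts[ci] - 1L, compl = !plus)
      } else {
        list(chrom = copy_chrom[ci], pos = ends[ci] + 1L, compl = !plus)
      }
    })
    eff <- vapply(slots, function(sl) {
      if (sl$pos < 1 || sl$pos > g$lengths[[sl$chrom]]) return(NA_character_)
      b <- substr(g$seq[[sl$chrom]], sl$pos, sl$pos)
      if (sl$compl) unname(comp[b]) else b
    }, character(1))
    for (ci in seq_along(slots)) {
      sl <- slots[[ci]]
      if (is.na(eff[ci])) next
      if (!eff[ci] %in% eff[-ci]) next
      if (in_planted(sl$chrom, sl$pos)) next
      choices <- setdiff(c("A", "C", "G", "T"), eff[-ci])
      if (length(choices) == 0) next  # > 4 copies: cannot separate all
      newb <- choices[[1L + floor(runif(1) * length(choices))]]
      eff[ci] <- newb
      raw <- if (sl$compl) unname(comp[newb]) else newb
      substr(g$seq[[sl$chrom]], sl$pos, sl$pos) <- raw
    }
  }
  g
}
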