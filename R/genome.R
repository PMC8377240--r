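#' Genome container
#'
#' A genome is an ordered set of uniquely named nucleotide sequences over the
#' alphabet \code{A, C, G, T, N}. Sequences are stored uppercase; coordinates
#' used throughout the package are 1-based and inclusive (the GRanges
#' convention); BED output is converted to 0-based half-open form by
#' \code{\link{write_bed}} and VCF positions are 1-based.
#'
#' @param seqs Named character vector of sequences (one element per
#'   chromosome). Names must be unique and sequences non-empty.
#' @return An object of class \code{mcr_genome}: a list with elements
#'   \code{seq} (named uppercase character vector) and \code{lengths}
#'   (named integer vector of sequence lengths in bp).
#' @examples
#' g <- genome(c(chr1 = "ACGTACGT", chr2 = "GGGCCC"))
#' genome_lengths(g)
#' @export
genome <- function(seqs) {
  if (length(seqs) == 0 || is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("genome requires a non-empty named character vector of sequences")
  if (anyDuplicated(names(seqs)))
    stop("sequence names must be unique")
  seqs <- setNames(toupper(as.character(seqs)), names(seqs))
  if (any(nchar(seqs) == 0))
    stop("sequences must be non-empty")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence '", names(seqs)[bad][1],
         "' contains characters outside {A,C,G,T,N}")
  structure(list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "mcr_genome")
}

#' @export
print.mcr_genome <- function(x, ...) {
  cat("<mcr_genome> ", length(x$seq), " sequence(s), ",
      format(sum(as.numeric(x$lengths)), big.mark = ","), " bp total\n", sep = "")
  for (nm in head(names(x$seq), 10))
    cat("  ", nm, ": ", format(x$lengths[[nm]], big.mark = ","), " bp\n", sep = "")
  if (length(x$seq) > 10) cat("  ...\n")
  invisible(x)
}

#' Genome sequence lengths
#' @param g An \code{mcr_genome}.
#' @return Named integer vector of per-chromosome lengths in bp.
#' @export
genome_lengths <- function(g) {
  stopifnot(inherits(g, "mcr_genome"))
  g$lengths
}

total_genome_length <- function(g) sum(as.numeric(g$lengths))

#' Read a genome from a FASTA file
#'
#' Reads a (multi-record) FASTA file via Biostrings, uppercases the sequences
#' and validates the alphabet. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return An \code{mcr_genome}.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # readDNAStringSet silently drops invalid letters with a warning; treat
  # any such warning as a format error so alphabet violations never pass
  ss <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop("malformed FASTA in '", path, "': ",
                                      conditionMessage(e))),
    warning = function(w) {
      if (grepl("invalid one-letter sequence code", conditionMessage(w)))
        stop("sequence in '", path,
             "' contains characters outside the DNA alphabet")
      invokeRestart("muffleWarning")
    })
  # drop descriptions after first whitespace, as aligners do
  nm <- sub("\\s.*$", "", names(ss))
  genome(setNames(as.character(ss), nm))
}

#' Write a genome to a FASTA file
#' @param g An \code{mcr_genome}.
#' @param path Output path.
#' @export
write_genome_fasta <- function(g, path) {
  stopifnot(inherits(g, "mcr_genome"))
  ss <- Biostrings::DNAStringSet(g$seq)
  Biostrings::writeXStringSet(ss, filepath = path, width = 70L)
  invisible(path)
}

# subsequence accessor, 1-based inclusive
genome_subseq <- function(g, chrom, start, end) {
  substr(g$seq[[chrom]], start, end)
}
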