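#' Write paired-end reads as two FASTQ files
#'
#' Emits standard 4-line FASTQ with identical mate order in both files and
#' \code{/1}, \code{/2} mate suffixes. Qualities default to a constant
#' configurable Phred score, matching the simulator's positional (not
#' quality-driven) error model.
#'
#' @param pairs A list or data frame with elements \code{read1} and
#'   \code{read2} (character vectors of equal length) and optionally
#'   \code{qual1}, \code{qual2} and \code{id}.
#' @param path_r1,path_r2 Output FASTQ paths.
#' @param phred Constant Phred quality used when no qualities are supplied
#'   (default 35).
#' @return Invisibly, \code{c(path_r1, path_r2)}.
#' @export
write_read_pairs <- function(pairs, path_r1, path_r2, phred = 35L) {
  r1 <- as.character(pairs$read1)
  r2 <- as.character(pairs$read2)
  if (length(r1) != length(r2)) stop("read1 and read2 must have equal length")
  n <- length(r1)
  qchar <- rawToChar(as.raw(33L + phred))
  q1 <- if (!is.null(pairs$qual1)) as.character(pairs$qual1) else
    vapply(nchar(r1), function(k) strrep(qchar, k), character(1))
  q2 <- if (!is.null(pairs$qual2)) as.character(pairs$qual2) else
    vapply(nchar(r2), function(k) strrep(qchar, k), character(1))
  if (any(nchar(q1) != nchar(r1)) || any(nchar(q2) != nchar(r2)))
    stop("quality string length must match sequence length")
  ids <- if (!is.null(pairs$id)) as.character(pairs$id) else
    if (n > 0) paste0("pair", seq_len(n)) else character(0)
  con1 <- file(path_r1, "w"); con2 <- file(path_r2, "w")
  on.exit({ close(con1); close(con2) })
  if (n > 0) {
    writeLines(as.vector(rbind(paste0("@", ids, "/1"), r1, "+", q1)), con1)
    writeLines(as.vector(rbind(paste0("@", ids, "/2"), r2, "+", q2)), con2)
  }
  invisible(c(path_r1, path_r2))
}

#' Read paired FASTQ files back into memory
#'
#' Parses the two mate files via Biostrings and checks that mate ordering is
#' consistent.
#'
#' @param path_r1,path_r2 FASTQ paths.
#' @return List with \code{read1}, \code{read2}, \code{qual1}, \code{qual2},
#'   \code{id}.
#' @export
read_read_pairs <- function(path_r1, path_r2) {
  read_fq <- function(p) withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(p),
    warning = function(w) {
      # harmless bookkeeping notice about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  s1 <- read_fq(path_r1)
  s2 <- read_fq(path_r2)
  if (length(s1) != length(s2))
    stop("mate files differ in record count")
  id1 <- sub("/1$", "", sub("\\s.*$", "", names(s1)))
  id2 <- sub("/2$", "", sub("\\s.*$", "", names(s2)))
  if (!identical(id1, id2))
    stop("mate order differs between files")
  list(read1 = unname(as.character(s1)), read2 = unname(as.character(s2)),
       qual1 = unname(as.character(Biostrings::quality(s1))),
       qual2 = unname(as.character(Biostrings::quality(s2))),
       id = id1)
}
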