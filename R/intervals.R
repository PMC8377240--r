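#' Build a genomic interval set
#'
#' Convenience constructor for the GRanges interval sets used throughout the
#' package. Coordinates are 1-based inclusive.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive.
#' @param name Optional labels (stored in the \code{name} metadata column).
#' @param strand Optional strand vector over \code{+,-,*}.
#' @param genome Optional \code{mcr_genome}; when given, intervals are
#'   validated against chromosome bounds.
#' @return A \code{GRanges}.
#' @export
intervals <- function(chrom, start, end, name = NULL, strand = NULL,
                      genome = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = if (is.null(strand)) "*" else strand)
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(genome)) validate_intervals(gr, genome)
  gr
}

# error when intervals are invalid or exceed chromosome bounds
validate_intervals <- function(gr, genome) {
  if (!inherits(genome, "mcr_genome"))
    stop("expected an mcr_genome")
  g <- genome
  chr <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chr), names(g$seq))
  if (length(unknown))
    stop("interval chromosome(s) not in genome: ",
         paste(unknown, collapse = ", "))
  if (any(GenomicRanges::start(gr) < 1L))
    stop("interval start below 1")
  if (any(GenomicRanges::end(gr) > g$lengths[chr]))
    stop("interval end exceeds chromosome length")
  invisible(gr)
}

#' Interval algebra over genomic interval sets
#'
#' Set operations on interval sets, validated against a common genome.
#' \code{union} returns the sorted, minimal, non-overlapping union of both
#' sets; \code{intersect} and \code{subtract} are the usual set operations on
#' covered bases; \code{coverage_fraction} is the total length of the union
#' divided by the total genome length.
#'
#' @param set_a,set_b \code{GRanges}. \code{set_b} may be \code{NULL} for
#'   \code{coverage_fraction}.
#' @param mode One of \code{"union"}, \code{"intersect"}, \code{"subtract"},
#'   \code{"coverage_fraction"}.
#' @param genome An \code{mcr_genome} the intervals must lie within.
#' @return A \code{GRanges}, or a single numeric in \code{[0, 1]} for
#'   \code{coverage_fraction}.
#' @examples
#' g <- genome(c(chr1 = strrep("A", 100)))
#' a <- intervals("chr1", 1, 10)
#' b <- intervals("chr1", 6, 15)
#' interval_algebra(a, b, "union", g)           # [1, 15]
#' interval_algebra(a, b, "coverage_fraction", g)  # 0.15
#' @export
interval_algebra <- function(set_a, set_b = NULL,
                             mode = c("union", "intersect", "subtract",
                                      "coverage_fraction"),
                             genome = NULL) {
  mode <- match.arg(mode)
  if (is.null(genome)) stop("interval_algebra requires a genome")
  validate_intervals(set_a, genome)
  if (!is.null(set_b)) validate_intervals(set_b, genome)
  lv <- names(genome$seq)
  a <- GenomicRanges::reduce(relevel_gr(set_a, lv))
  b <- if (is.null(set_b)) relevel_gr(GenomicRanges::GRanges(), lv) else
    GenomicRanges::reduce(relevel_gr(set_b, lv))
  switch(mode,
    union = GenomicRanges::reduce(c(a, b)),
    intersect = GenomicRanges::intersect(a, b),
    subtract = GenomicRanges::setdiff(a, b),
    coverage_fraction = {
      u <- GenomicRanges::reduce(c(a, b))
      sum(as.numeric(GenomicRanges::width(u))) / total_genome_length(genome)
    })
}

# strip strand and metadata so reduce/setdiff operate on covered bases
unstrand_drop <- function(gr) {
  gr <- GenomicRanges::granges(gr)
  GenomicRanges::strand(gr) <- "*"
  gr
}

# rebuild a GRanges on a fixed chromosome-level ordering (the genome's), so
# that set operations sort deterministically and combine without seqinfo
# mismatch warnings; strand and metadata are dropped
relevel_gr <- function(gr, levels) {
  GenomicRanges::GRanges(
    factor(as.character(GenomicRanges::seqnames(gr)), levels = levels),
    GenomicRanges::ranges(gr))
}

#' Read a BED file as a GRanges
#'
#' BED is 0-based half-open on disk; the returned GRanges is 1-based
#' inclusive (conversion by rtracklayer).
#'
#' @param path Path to a BED3/BED6 file.
#' @return A \code{GRanges} (with \code{name}, \code{score} metadata when
#'   present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  rtracklayer::import(path, format = "BED")
}

#' Write a GRanges to a BED file
#'
#' Emits BED6 when name/strand information is present, BED3 otherwise
#' (conversion to 0-based half-open by rtracklayer).
#'
#' @param gr A \code{GRanges}; a \code{name} metadata column becomes the BED
#'   name field.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
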