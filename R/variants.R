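#' Variant tables
#'
#' Variants are plain data frames with columns \code{chrom}, \code{pos}
#' (1-based), \code{ref}, \code{alt} (single bases), and optionally
#' \code{genotype} (\code{"het"} or \code{"hom"}) plus a \code{stratum}
#' label. [write_vcf_variants()] renders such a table as a minimal VCF v4.2
#' file (CHROM POS ID REF ALT QUAL FILTER INFO and, when genotypes are
#' present, FORMAT + one sample column with GT); [read_vcf_variants()] reads
#' that subset back. Multi-allelic records and indels are out of scope.
#'
#' @param variants Data frame as described above.
#' @param path File path.
#' @param genome Optional \code{mcr_genome} used to emit \code{##contig}
#'   header lines and validate positions.
#' @param sample_name Sample column name used when genotypes are written.
#' @return \code{read_vcf_variants} returns the variant data frame (with a
#'   \code{genotype} column when the file has GT fields);
#'   \code{write_vcf_variants} returns \code{path} invisibly.
#' @name vcf_io
NULL

validate_variants <- function(variants, genome = NULL) {
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants)))
    stop("variant table needs columns: ", paste(req, collapse = ", "))
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$ref == variants$alt))
    stop("ref and alt must differ")
  if (any(!variants$ref %in% c("A", "C", "G", "T")) ||
      any(!variants$alt %in% c("A", "C", "G", "T")))
    stop("ref/alt must be single bases in {A,C,G,T}")
  if (!is.null(genome)) {
    chr <- as.character(variants$chrom)
    unknown <- setdiff(unique(chr), names(genome$seq))
    if (length(unknown))
      stop("variant chromosome(s) not in genome: ",
           paste(unknown, collapse = ", "))
    if (any(variants$pos < 1L) || any(variants$pos > genome$lengths[chr]))
      stop("variant position outside chromosome")
  }
  invisible(variants)
}

#' @rdname vcf_io
#' @export
write_vcf_variants <- function(variants, path, genome = NULL,
                               sample_name = "sample") {
  validate_variants(variants, genome)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mcrscan")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(genome$seq), unname(genome$lengths)))
  has_gt <- "genotype" %in% names(variants) && nrow(variants) > 0 &&
    !all(is.na(variants$genotype))
  has_str <- "stratum" %in% names(variants)
  if (has_str)
    hdr <- c(hdr, paste0("##INFO=<ID=STR,Number=1,Type=String,",
                         "Description=\"Region stratum\">"))
  if (has_gt)
    hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (has_gt) cols <- c(cols, "FORMAT", sample_name)
  hdr <- c(hdr, paste(cols, collapse = "\t"))

  n <- nrow(variants)
  if (n > 0) {
    info <- if (has_str) paste0("STR=", variants$stratum) else rep(".", n)
    body <- paste(variants$chrom, variants$pos,
                  if ("id" %in% names(variants)) variants$id else rep(".", n),
                  variants$ref, variants$alt, ".", "PASS", info, sep = "\t")
    if (has_gt) {
      gt <- ifelse(is.na(variants$genotype), "./.",
                   ifelse(variants$genotype == "hom", "1/1", "0/1"))
      body <- paste(body, "GT", gt, sep = "\t")
    }
    writeLines(c(hdr, body), path)
  } else {
    writeLines(hdr, path)
  }
  invisible(path)
}

#' @rdname vcf_io
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), genotype = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8)) stop("malformed VCF record (fewer than 8 fields) at line ",
                        which(nf < 8)[1])
  m <- do.call(rbind, lapply(fields, function(x) x[1:8]))
  out <- data.frame(chrom = m[, 1], pos = as.integer(m[, 2]), ref = m[, 4],
                    alt = m[, 5], stringsAsFactors = FALSE)
  # genotype from first sample's GT field, when present
  out$genotype <- NA_character_
  has10 <- nf >= 10
  if (any(has10)) {
    gt <- vapply(fields[has10], function(x) {
      fmt <- strsplit(x[9], ":", fixed = TRUE)[[1]]
      i <- match("GT", fmt)
      if (is.na(i)) return(NA_character_)
      strsplit(x[10], ":", fixed = TRUE)[[1]][i]
    }, character(1))
    out$genotype[has10] <- ifelse(gt %in% c("1/1", "1|1"), "hom",
                           ifelse(gt %in% c("0/1", "1/0", "0|1", "1|0"),
                                  "het", NA_character_))
  }
  info <- m[, 8]
  str <- sub(".*STR=([^;]+).*", "\\1", info)
  str[!grepl("STR=", info)] <- NA_character_
  if (any(!is.na(str))) out$stratum <- str
  out
}

#' Extract the variants falling inside a region set
#'
#' Implements the VCF-by-BED filter utility: keeps exactly the VCF records
#' whose (1-based) position falls inside some region, preserving input
#' order. Records on chromosomes absent from the region set's namespace (the
#' genome when given, else the region chromosomes) are skipped with a
#' warning and counted in the \code{skipped_chroms} attribute.
#'
#' @param vcf Path to a VCF file, or a variant data frame.
#' @param regions A \code{GRanges}, or path to a BED file.
#' @param genome Optional \code{mcr_genome} defining the chromosome
#'   namespace.
#' @param out_vcf Optional path; when given, retained records are also
#'   written as a VCF.
#' @return Data frame of retained variants (attribute
#'   \code{skipped_chroms}: named count of records skipped per unknown
#'   chromosome).
#' @export
extract_variants_in_regions <- function(vcf, regions, genome = NULL,
                                        out_vcf = NULL) {
  v <- if (is.character(vcf)) read_vcf_variants(vcf) else vcf
  validate_variants(v)
  gr <- if (is.character(regions)) read_bed(regions) else regions
  namespace <- if (!is.null(genome)) names(genome$seq) else
    unique(as.character(GenomicRanges::seqnames(gr)))
  known <- as.character(v$chrom) %in% namespace
  skipped <- table(as.character(v$chrom)[!known])
  if (any(!known))
    warning(sum(!known), " record(s) on chromosome(s) outside the namespace ",
            "were skipped: ", paste(names(skipped), collapse = ", "))
  v2 <- v[known, , drop = FALSE]
  keep <- logical(nrow(v2))
  if (nrow(v2) > 0) {
    vgr <- GenomicRanges::GRanges(v2$chrom, IRanges::IRanges(v2$pos, v2$pos))
    keep <- IRanges::overlapsAny(vgr, gr, ignore.strand = TRUE)
  }
  out <- v2[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped_chroms") <- skipped
  if (!is.null(out_vcf)) write_vcf_variants(out, out_vcf, genome)
  out
}

#' Assign a stratum label to positions
#'
#' @param chrom,pos Vectors of positions (1-based).
#' @param strata Named list of \code{GRanges} (e.g. \code{list(MCR = ...,
#'   flank = ...)}).
#' @param other Label used for positions in none of the strata.
#' @return Character vector of stratum labels.
#' @export
stratum_of <- function(chrom, pos, strata, other = "other") {
  out <- rep(other, length(chrom))
  if (length(chrom) == 0) return(out)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  for (nm in names(strata)) {
    hit <- IRanges::overlapsAny(gr, strata[[nm]], ignore.strand = TRUE)
    out[hit & out == other] <- nm
  }
  out
}
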