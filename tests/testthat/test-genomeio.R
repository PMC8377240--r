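test_that("FASTA reading normalises case, preserves order and checks the alphabet", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT"), fa)
  g <- read_genome_fasta(fa)
  expect_identical(names(g$seq), "chr1")
  expect_identical(unname(g$lengths), 4L)

  writeLines(c(">b_first desc ignored", "acgtn", ">a_second", "ggcc"), fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(names(g2$seq), c("b_first", "a_second"))
  expect_identical(unname(g2$seq[1]), "ACGTN")

  writeLines(c(">chr1", "ACGX"), fa)
  expect_error(read_genome_fasta(fa), "outside")

  expect_error(genome(c("ACGT")), "named")
  expect_error(genome(c(a = "ACGT", a = "GG")), "unique")
})

test_that("FASTA writing round-trips through Biostrings", {
  g <- genome(c(chr1 = random_dna(157, seed = 1), chr2 = random_dna(80, seed = 2)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, fa)
  g2 <- read_genome_fasta(fa)
  expect_identical(g$seq, g2$seq)
})

test_that("paired FASTQ writing produces valid 4-line records that round-trip", {
  p <- list(read1 = random_dna(75, seed = 3), read2 = random_dna(75, seed = 4))
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fq")
  write_read_pairs(p, f1, f2)
  l1 <- readLines(f1); l2 <- readLines(f2)
  expect_length(l1, 4L)
  expect_length(l2, 4L)
  expect_match(l1[1], "/1$")
  expect_match(l2[1], "/2$")
  expect_identical(nchar(l1[4]), 75L)  # constant-quality string

  # empty set -> two empty files
  write_read_pairs(list(read1 = character(0), read2 = character(0)), f1, f2)
  expect_identical(file.size(f1), 0)
  expect_identical(file.size(f2), 0)

  # round trip of many pairs, including via an independent parser
  set.seed(9)
  pp <- list(read1 = vapply(1:20, function(i) random_dna(60), character(1)),
             read2 = vapply(1:20, function(i) random_dna(60), character(1)))
  write_read_pairs(pp, f1, f2)
  back <- read_read_pairs(f1, f2)
  expect_identical(back$read1, pp$read1)
  expect_identical(back$read2, pp$read2)
  bio <- as.character(Biostrings::readDNAStringSet(f1, format = "fastq"))
  expect_identical(unname(bio), pp$read1)

  expect_error(write_read_pairs(list(read1 = "ACGT", read2 = "ACGT",
                                     qual1 = "III", qual2 = "IIII"),
                                f1, f2), "length")
})

test_that("interval algebra matches hand arithmetic and respects bounds", {
  g <- genome(c(chr1 = random_dna(100, seed = 5)))
  a <- intervals("chr1", 1, 10)
  b <- intervals("chr1", 6, 15)
  u <- interval_algebra(a, b, "union", g)
  expect_identical(GenomicRanges::start(u), 1L)
  expect_identical(GenomicRanges::end(u), 15L)
  expect_equal(interval_algebra(a, b, "coverage_fraction", g), 0.15)

  d1 <- intervals("chr1", 1, 10); d2 <- intervals("chr1", 50, 60)
  expect_length(interval_algebra(d1, d2, "intersect", g), 0L)

  expect_error(interval_algebra(intervals("chr1", 90, 110), NULL,
                                "coverage_fraction", g), "exceeds")
})

test_that("interval algebra agrees with a per-base bitmap oracle", {
  g <- genome(c(chr1 = random_dna(6000, seed = 6),
                chr2 = random_dna(4000, seed = 7)))
  set.seed(8)
  for (i in 1:15) {
    a <- random_interval_set(g, sample(1:8, 1))
    b <- random_interval_set(g, sample(1:8, 1))
    for (mode in c("union", "intersect", "subtract")) {
      got <- interval_algebra(a, b, mode, g)
      want <- bitmap_algebra(a, b, mode, g)
      expect_true(identical(as.character(got), as.character(want)),
                  label = paste("mode", mode, "case", i))
    }
    expect_equal(interval_algebra(a, b, "coverage_fraction", g),
                 bitmap_algebra(a, b, "coverage_fraction", g))
  }
})

test_that("BED round-trips preserve the 0-based half-open convention", {
  g <- genome(c(chr1 = random_dna(5000, seed = 10)))
  gr <- intervals("chr1", c(100, 1000), c(199, 2000),
                  name = c("a", "b"), strand = c("+", "-"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, bed)
  raw <- read.table(bed, sep = "\t")
  expect_identical(raw$V2, c(99L, 999L))   # 0-based starts on disk
  expect_identical(raw$V3, c(199L, 2000L)) # exclusive ends on disk
  back <- read_bed(bed)
  expect_identical(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_identical(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_identical(back$name, c("a", "b"))
  # random intervals: write -> read is the identity on coordinates
  set.seed(11)
  r <- random_interval_set(g, 20)
  write_bed(r, bed)
  rb <- read_bed(bed)
  expect_identical(as.character(GenomicRanges::granges(rb)),
                   as.character(GenomicRanges::granges(r)))
})

test_that("minimal VCF writer/reader round-trips and matches vcfR", {
  g <- genome(c(chr1 = random_dna(2000, seed = 12)))
  v <- data.frame(chrom = "chr1", pos = c(5L, 100L, 1999L),
                  ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                  genotype = c("het", "hom", "het"),
                  stratum = c("MCR", "flank", "MCR"),
                  stringsAsFactors = FALSE)
  v$ref <- substring(g$seq[["chr1"]], v$pos, v$pos)
  v$alt <- vapply(v$ref, function(r)
    setdiff(c("A", "C", "G", "T"), r)[1], character(1), USE.NAMES = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_variants(v, f, g)
  back <- read_vcf_variants(f)
  expect_identical(back$pos, v$pos)
  expect_identical(back$ref, v$ref)
  expect_identical(back$alt, v$alt)
  expect_identical(back$genotype, v$genotype)
  expect_identical(back$stratum, v$stratum)

  vr <- vcfR::read.vcfR(f, verbose = FALSE)
  expect_identical(as.integer(vr@fix[, "POS"]), v$pos)
  expect_identical(unname(vr@fix[, "REF"]), v$ref)
  expect_identical(unname(vr@fix[, "ALT"]), v$alt)
  gt <- vcfR::extract.gt(vr)
  expect_identical(unname(gt[, 1]), c("0/1", "1/1", "0/1"))
})

test_that("variant extraction honours VCF/BED coordinate conventions", {
  bed <- withr::local_tempfile(fileext = ".bed")
  v <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  writeLines("chr1\t99\t100", bed)   # half-open [99,100) = 1-based pos 100
  expect_identical(nrow(extract_variants_in_regions(v, bed)), 1L)
  writeLines("chr1\t100\t200", bed)  # [100,200) = 1-based 101..200
  expect_identical(nrow(extract_variants_in_regions(v, bed)), 0L)
  writeLines("chr1\t0\t99", bed)     # 1-based 1..99
  expect_identical(nrow(extract_variants_in_regions(v, bed)), 0L)
  writeLines("chr1\t0\t100", bed)    # 1-based 1..100
  expect_identical(nrow(extract_variants_in_regions(v, bed)), 1L)
})

test_that("variant extraction equals a per-base membership oracle", {
  g <- genome(c(chr1 = random_dna(20000, seed = 13),
                chr2 = random_dna(20000, seed = 14)))
  set.seed(15)
  regions <- random_interval_set(g, 25)
  n <- 1000
  chr <- sample(names(g$seq), n, replace = TRUE)
  pos <- vapply(chr, function(cn) sample.int(g$lengths[[cn]], 1L),
                integer(1), USE.NAMES = FALSE)
  v <- data.frame(chrom = chr, pos = pos, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  v <- v[!duplicated(paste(v$chrom, v$pos)), ]
  got <- extract_variants_in_regions(v, regions, genome = g)
  bm <- bitmap_of(regions, g)
  want <- vapply(seq_len(nrow(v)), function(i) bm[[v$chrom[i]]][v$pos[i]],
                 logical(1))
  expect_identical(paste(got$chrom, got$pos),
                   paste(v$chrom[want], v$pos[want]))
  # input order is preserved
  expect_false(is.unsorted(match(paste(got$chrom, got$pos),
                                 paste(v$chrom, v$pos))))
})

test_that("whole-genome and empty region sets behave as limits; unknown chroms are skipped with a count", {
  g <- genome(c(chr1 = random_dna(1000, seed = 16)))
  v <- data.frame(chrom = c("chr1", "chr1", "chrUn"),
                  pos = c(10L, 999L, 5L), ref = "A", alt = "C",
                  stringsAsFactors = FALSE)
  whole <- intervals("chr1", 1, 1000)
  expect_warning(out <- extract_variants_in_regions(v, whole, genome = g),
                 "skipped")
  expect_identical(nrow(out), 2L)
  expect_identical(as.integer(attr(out, "skipped_chroms")[["chrUn"]]), 1L)
  empty <- GenomicRanges::GRanges()
  out2 <- suppressWarnings(extract_variants_in_regions(v[1:2, ], empty,
                                                       genome = g))
  expect_identical(nrow(out2), 0L)
})
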