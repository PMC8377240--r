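# Fixture: genome with one exact 3 kb two-copy repeat and unique background.
repeat_genome <- function(seed = 1, rep_len = 3000L, gap = 2500L) {
  set.seed(seed)
  S <- random_dna(rep_len)
  genome(c(chr1 = paste0(random_dna(gap), "G", S, "A", random_dna(gap)),
           chr2 = paste0(random_dna(gap), "T", S, "C", random_dna(gap))))
}

test_that("index construction validates k and reports full position lists", {
  g <- genome(c(chr1 = random_dna(1000, seed = 71)))
  expect_error(build_index(g, k = 30), "odd")
  expect_error(build_index(g, k = 13), "between")
  expect_error(build_index(g, k = 65), "between")
  idx <- build_index(g, k = 31)
  # random 1 kb genome: every 31-mer unique
  set.seed(72)
  for (p in sample(1:(1000 - 30), 40)) {
    hits <- index_lookup(idx, substring(g$seq[["chr1"]], p, p + 30))
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$start, p)
  }
})

test_that("interior k-mers of an exact duplicate report every occurrence", {
  g <- repeat_genome(seed = 73, rep_len = 400L, gap = 1200L)
  idx <- build_index(g, k = 31)
  # k-mer from the repeat interior occurs at both planted loci
  km <- substring(g$seq[["chr1"]], 1202 + 100, 1202 + 130)
  hits <- index_lookup(idx, km)
  expect_identical(nrow(hits), 2L)
  expect_setequal(hits$chrom, c("chr1", "chr2"))
})

test_that("error-free pairs from unique sequence map uniquely to their origin", {
  g <- genome(c(chr1 = random_dna(50000, seed = 74)))
  pr <- simulate_read_pairs(g, sim_strategy(100, 3, error_rate = 0),
                            seed = 75)
  idx <- build_index(g)
  aln <- map_read_pairs(pr, idx)
  expect_true(all(aln$mapped))
  expect_true(all(aln$unique))
  expect_true(all(aln$mismatches == 0L))
  left <- pmin(aln$pos1, aln$pos2)
  expect_identical(left, pr$truth$frag_start)
})

test_that("pairs wholly inside an exact repeat are discarded as non-unique, anchored pairs are kept", {
  g <- repeat_genome(seed = 76)
  idx <- build_index(g)
  S_start <- 2502L  # first copy start on chr1
  frag <- 400L
  # both mates inside copy 1 -> two co-optimal placements
  inner_start <- S_start + 1000L
  r1 <- substring(g$seq[["chr1"]], inner_start, inner_start + 99L)
  r2 <- mcrscan:::rc_string(substring(g$seq[["chr1"]],
                                      inner_start + frag - 100L,
                                      inner_start + frag - 1L))
  aln <- map_read_pairs(list(read1 = r1, read2 = r2), idx)
  expect_true(aln$mapped)
  expect_false(aln$unique)
  expect_identical(aln$n_best, 2L)

  # one mate anchored in the unique flank -> single optimum
  edge_start <- S_start - 200L
  r1f <- substring(g$seq[["chr1"]], edge_start, edge_start + 99L)
  r2f <- mcrscan:::rc_string(substring(g$seq[["chr1"]],
                                       edge_start + frag - 100L,
                                       edge_start + frag - 1L))
  aln2 <- map_read_pairs(list(read1 = r1f, read2 = r2f), idx)
  expect_true(aln2$unique)
  expect_identical(aln2$chrom, "chr1")
  expect_identical(aln2$pos1, edge_start)

  # both agree with the exhaustive placement oracle
  small <- genome(c(chr1 = substring(g$seq[["chr1"]], 1, 8000)))
  idx_s <- build_index(small)
  set.seed(77)
  for (start in c(3500L, 2302L, 800L)) {
    rr1 <- substring(small$seq[["chr1"]], start, start + 74L)
    rr2 <- mcrscan:::rc_string(substring(small$seq[["chr1"]],
                                         start + 325L, start + 399L))
    got <- map_read_pairs(list(read1 = rr1, read2 = rr2), idx_s,
                          max_mismatch = 3)
    want <- exhaustive_placements(small, rr1, rr2, max_mm = 3)
    expect_identical(got$n_best, want$count, label = paste("start", start))
    if (got$mapped) expect_identical(got$mismatches, as.integer(want$best))
  }
})

test_that("pileup counts and calls follow the threshold predicate", {
  g <- genome(c(chr1 = random_dna(400, seed = 78)))
  ref20 <- substring(g$seq[["chr1"]], 101, 120)
  alt_base <- setdiff(c("A", "C", "G", "T"), substring(ref20, 11, 11))[1]
  alt_read <- ref20
  substr(alt_read, 11, 11) <- alt_base
  pairs <- list(read1 = c(rep(ref20, 5), rep(alt_read, 5)),
                read2 = rep("X", 10))  # mate 2 unused below
  aln <- data.frame(pair = 1:10, mapped = TRUE, unique = TRUE,
                    chrom = "chr1", pos1 = 101L, strand1 = "+",
                    pos2 = NA_integer_, strand2 = NA_character_,
                    mismatches = 0L, n_best = 1L, stringsAsFactors = FALSE)
  class(aln) <- c("alignments", "data.frame")
  counts <- pileup_counts(aln, pairs, g)
  site <- counts[counts$pos == 111L, ]
  expect_identical(site$depth, 10L)
  expect_identical(site[[alt_base]], 5L)
  calls <- pileup_and_call(aln, pairs, g)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$pos, 111L)
  expect_identical(calls$alt, alt_base)
  expect_identical(calls$genotype, "het")    # fraction 0.5 < 0.8
  expect_identical(calls$depth, 10L)

  # depth 3 -> no call
  aln3 <- aln[1:3, ]; class(aln3) <- c("alignments", "data.frame")
  pairs3 <- list(read1 = rep(alt_read, 3), read2 = rep("X", 3))
  aln3$pair <- 1:3
  expect_identical(nrow(pileup_and_call(aln3, pairs3, g)), 0L)

  # hom genotype at fraction >= 0.8
  pairs_h <- list(read1 = c(rep(ref20, 2), rep(alt_read, 8)),
                  read2 = rep("X", 10))
  calls_h <- pileup_and_call(aln, pairs_h, g)
  expect_identical(calls_h$genotype, "hom")
})

test_that("randomized pileups match an independent reimplementation of the caller predicate", {
  g <- genome(c(chr1 = random_dna(3000, seed = 79)))
  set.seed(80)
  n_reads <- 120
  starts <- sample(1:(3000 - 30), n_reads, replace = TRUE)
  reads <- substring(g$seq[["chr1"]], starts, starts + 29L)
  # inject random substitutions into ~half the reads
  for (i in sample(n_reads, 60)) {
    p <- sample(30, 1)
    old <- substring(reads[i], p, p)
    substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  aln <- data.frame(pair = seq_len(n_reads), mapped = TRUE, unique = TRUE,
                    chrom = "chr1", pos1 = starts, strand1 = "+",
                    pos2 = NA_integer_, strand2 = NA_character_,
                    mismatches = 0L, n_best = 1L, stringsAsFactors = FALSE)
  class(aln) <- c("alignments", "data.frame")
  pairs <- list(read1 = reads, read2 = rep("X", n_reads))
  counts <- pileup_counts(aln, pairs, g, min_depth = 1)
  calls <- pileup_and_call(aln, pairs, g)

  # independent predicate over the counts table
  predicate <- function(row) {
    depth <- row$A + row$C + row$G + row$T
    cc <- c(A = row$A, C = row$C, G = row$G, T = row$T)
    cc <- cc[names(cc) != row$ref]
    alt <- names(cc)[which.max(cc)]  # which.max keeps lexicographic first
    altc <- max(cc)
    if (depth >= 4 && altc >= 2 && altc / depth >= 0.2)
      data.frame(pos = row$pos, alt = alt,
                 genotype = if (altc / depth >= 0.8) "hom" else "het",
                 stringsAsFactors = FALSE)
    else NULL
  }
  want <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    predicate(counts[i, ])))
  if (is.null(want)) {
    expect_identical(nrow(calls), 0L)
  } else {
    expect_identical(calls$pos, want$pos)
    expect_identical(calls$alt, want$alt)
    expect_identical(calls$genotype, want$genotype)
  }
})

test_that("mate-2 strand contributions are complemented into the pileup", {
  g <- genome(c(chr1 = random_dna(500, seed = 81)))
  seg <- substring(g$seq[["chr1"]], 201, 230)
  aln <- data.frame(pair = 1L, mapped = TRUE, unique = TRUE, chrom = "chr1",
                    pos1 = 201L, strand1 = "-", pos2 = NA_integer_,
                    strand2 = NA_character_, mismatches = 0L, n_best = 1L,
                    stringsAsFactors = FALSE)
  class(aln) <- c("alignments", "data.frame")
  pairs <- list(read1 = mcrscan:::rc_string(seg), read2 = "X")
  counts <- pileup_counts(aln, pairs, g)
  expect_identical(nrow(counts), 30L)
  # every contributed base equals the reference (read was the RC of it)
  for (i in seq_len(nrow(counts)))
    expect_identical(counts[[counts$ref[i]]][i], 1L)
})
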