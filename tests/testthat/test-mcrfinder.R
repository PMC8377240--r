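# Fixture: genome B1 + S + B2 + S + B3 with controlled junction letters so
# the planted segment is exactly the maximal repeat.
two_copy_genome <- function(seg_len, seed = 1, gap = 1500L) {
  set.seed(seed)
  S <- random_dna(seg_len)
  b <- function(n) random_dna(n)
  # distinct extension letters on both sides of the two copies
  genome(c(chr1 = paste0(b(gap), "G", S, "A", b(gap), "T", S, "C", b(gap))))
}

test_that("random genomes contain no multi-hit seed windows", {
  g <- generate_background(c(chr1 = 100000L), seed = 31)
  hits <- enumerate_seed_hits(g)
  expect_identical(nrow(hits), 0L)
  expect_identical(nrow(merge_seed_runs(hits)$groups), 0L)
})

test_that("a planted segment yields exactly len - w + 1 multi-hit windows per copy", {
  g <- two_copy_genome(400, seed = 32)
  hits <- enumerate_seed_hits(g, window = 300)
  # each copy contributes 101 windows (offsets 0..100), each with 2 occurrences
  expect_identical(nrow(hits), 2L * 101L * 2L)
  per_seed <- table(hits$seed_start)
  expect_true(all(per_seed == 2L))
  expect_identical(length(per_seed), 202L)
  # window-count arithmetic: a 1000 bp chromosome has 701 candidate windows
  g2 <- genome(c(chr1 = random_dna(1000, seed = 33)))
  expect_identical(attr(enumerate_seed_hits(g2), "n_windows"), 701L)
  expect_error(enumerate_seed_hits(g2, window = 1001), "longest")
})

test_that("run merging recovers a two-copy segment as one maximal group", {
  set.seed(34)
  S <- random_dna(310)
  g <- genome(c(chr1 = paste0(random_dna(1200), "G", S, "A", random_dna(400)),
                chr2 = paste0(random_dna(2000), "T", S, "C", random_dna(900))))
  m <- find_mcrs(g)
  expect_identical(nrow(m$groups), 1L)
  expect_identical(m$groups$length, 310L)
  expect_identical(m$groups$n_loci, 2L)
  expect_setequal(m$loci$chrom, c("chr1", "chr2"))
  expect_identical(m$loci$start[m$loci$chrom == "chr1"], 1202L)
  expect_identical(m$loci$start[m$loci$chrom == "chr2"], 2002L)
  # agrees with the brute-force oracle
  expect_identical(canon_groups(m), canon_groups(brute_force_repeat_oracle(g)))
})

test_that("finder and brute-force oracle are set-identical across randomized builds", {
  for (s in 1:8) {
    tb <- random_truth_build(3000 + s)
    m <- find_mcrs(tb$genome)
    o <- brute_force_repeat_oracle(tb$genome)
    expect_identical(canon_groups(m), canon_groups(o), label = paste("seed", s))
  }
})

test_that("exact truth recovery holds for clean planted builds", {
  # <= 4 copies per group, dispersed or 2-copy tandem: finder output should
  # equal the planted truth as a set of loci
  for (s in 1:5) {
    tb <- random_truth_build(4000 + s, len_range = c(300L, 900L))
    m <- find_mcrs(tb$genome)
    expect_identical(canon_groups(m), canon_truth(tb), label = paste("seed", s))
  }
})

test_that("the window length is a sharp detection threshold", {
  g299 <- two_copy_genome(299, seed = 35)
  expect_identical(nrow(find_mcrs(g299)$groups), 0L)
  g300 <- two_copy_genome(300, seed = 36)
  m <- find_mcrs(g300)
  expect_identical(m$groups$length, 300L)
})

test_that("minus-strand copies require strand_mode 'both'", {
  bg <- generate_background(c(chr1 = 8000L, chr2 = 8000L), seed = 37)
  tb <- plant_duplications(bg, duplication_spec(400, 2, "inter",
                                                strands = "-"), seed = 38)
  m_both <- find_mcrs(tb$genome, strand_mode = "both")
  expect_identical(nrow(m_both$groups), 1L)
  expect_setequal(m_both$loci$strand, c("+", "-"))
  m_fwd <- find_mcrs(tb$genome, strand_mode = "forward")
  expect_identical(nrow(m_fwd$groups), 0L)
})

test_that("reported groups are maximal and internally identical", {
  for (s in 1:3) {
    tb <- random_truth_build(5000 + s, len_range = c(300L, 800L))
    m <- find_mcrs(tb$genome)
    for (gid in m$groups$group_id) {
      lo <- m$loci[m$loci$group_id == gid, ]
      seqs <- vapply(seq_len(nrow(lo)), function(i)
        locus_seq(tb$genome, lo$chrom[i], lo$start[i], lo$end[i],
                  lo$strand[i]), character(1))
      expect_identical(length(unique(seqs)), 1L)
      # extending every locus by one base on either side breaks identity
      for (side in c("left", "right")) {
        ext <- vapply(seq_len(nrow(lo)), function(i) {
          plus <- lo$strand[i] == "+"
          grow_left <- xor(side == "right", plus)
          s2 <- lo$start[i] - as.integer(grow_left)
          e2 <- lo$end[i] + as.integer(!grow_left)
          if (s2 < 1 || e2 > tb$genome$lengths[[lo$chrom[i]]])
            return(NA_character_)
          locus_seq(tb$genome, lo$chrom[i], s2, e2, lo$strand[i])
        }, character(1))
        expect_false(length(unique(ext[!is.na(ext)])) == 1L &&
                       !anyNA(ext),
                     label = paste("seed", s, "group", gid, side))
      }
    }
  }
})

test_that("diverged copies are never reported as one full-length group", {
  for (s in 1:5) {
    bg <- generate_background(c(chr1 = 10000L, chr2 = 10000L), seed = 6000 + s)
    tb <- plant_duplications(bg, duplication_spec(600, 2, "inter",
                                                  divergence = 0.02),
                             seed = 7000 + s)
    if (nrow(tb$substitutions) == 0) next
    m <- find_mcrs(tb$genome)
    expect_true(all(m$groups$length < 600L),
                label = paste("seed", s))
  }
})

test_that("adding an exact copy never decreases a group's locus count", {
  set.seed(39)
  S <- random_dna(450)
  b1 <- random_dna(2000); b2 <- random_dna(2000); b3 <- random_dna(2000)
  g2 <- genome(c(chr1 = paste0(b1, "A", S, "G", b2),
                 chr2 = paste0(b3, "C", S, "T", random_dna(1500))))
  g3 <- genome(c(chr1 = paste0(b1, "A", S, "G", b2),
                 chr2 = paste0(b3, "C", S, "T", random_dna(500), "G", S,
                               "A", random_dna(1000))))
  m2 <- find_mcrs(g2); m3 <- find_mcrs(g3)
  expect_identical(m2$groups$n_loci, 2L)
  expect_identical(m3$groups$n_loci, 3L)
  expect_identical(m3$groups$length, 450L)
})

test_that("windows containing N are skipped", {
  g <- two_copy_genome(700, seed = 40)
  s <- g$seq[["chr1"]]
  # N in the middle of the first copy breaks it into sub-blocks < 700
  substr(s, 1502 + 350, 1502 + 350) <- "N"
  gN <- genome(c(chr1 = s))
  m <- find_mcrs(gN)
  expect_true(all(m$groups$length < 700L))
  for (i in seq_len(nrow(m$loci)))
    expect_false(grepl("N", locus_seq(gN, m$loci$chrom[i], m$loci$start[i],
                                      m$loci$end[i], m$loci$strand[i]),
                       fixed = TRUE))
})

test_that("summaries report coverage, histograms and chromosome classification", {
  g <- genome(c(chr1 = random_dna(60000, seed = 41),
                chr2 = random_dna(40000, seed = 42)))
  loci <- data.frame(group_id = c(1L, 1L), chrom = c("chr1", "chr2"),
                     start = c(1001L, 2001L), end = c(1400L, 2400L),
                     strand = "+", stringsAsFactors = FALSE)
  groups <- data.frame(group_id = 1L, length = 400L, n_loci = 2L)
  x <- mcrscan:::new_mcs_groups(groups, loci, 300L, "both", names(g$seq))
  sm <- summarize_mcrs(x, g)
  expect_equal(sm$coverage, 800 / 100000)
  expect_identical(unname(sm$classification), "inter")
  expect_identical(sum(sm$length_hist), 1L)
  expect_identical(as.integer(sm$copy_hist[["2"]]), 1L)

  empty <- mcrscan:::new_mcs_groups(
    data.frame(group_id = integer(), length = integer(),
               n_loci = integer()),
    data.frame(group_id = integer(), chrom = character(), start = integer(),
               end = integer(), strand = character(),
               stringsAsFactors = FALSE), 300L, "both", names(g$seq))
  sm0 <- summarize_mcrs(empty, g)
  expect_identical(sm0$coverage, 0)

  # randomized group sets: coverage equals the bitmap union
  set.seed(43)
  for (i in 1:5) {
    tb <- random_truth_build(8000 + i)
    m <- find_mcrs(tb$genome)
    if (nrow(m$groups) == 0) next
    sm2 <- summarize_mcrs(m, tb$genome)
    bm <- bitmap_of(mcr_loci(m), tb$genome)
    expect_equal(sm2$coverage,
                 sum(vapply(bm, sum, numeric(1))) /
                   sum(as.numeric(tb$genome$lengths)))
  }
})
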