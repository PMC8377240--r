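#' Classify called variants against planted truth
#'
#' A called variant is a true positive iff a truth variant exists with the
#' same chromosome, position and alternate allele (and genotype, when
#' \code{match_on_genotype}). False positives are the remaining calls;
#' false negatives the remaining truth variants. Genotype concordance among
#' true positives is reported separately.
#'
#' @param truth,called Variant data frames (one record per position within
#'   each set; duplicates are an error).
#' @param match_on_genotype Require genotype identity for a TP (default
#'   \code{FALSE}).
#' @return List with \code{tp}, \code{fp}, \code{fn} (data frames) and
#'   \code{genotype_concordance} (fraction of TP with matching genotype,
#'   \code{NA} when there are none or genotypes are absent).
#' @export
classify_calls <- function(truth, called, match_on_genotype = FALSE) {
  for (nm in c("truth", "called")) {
    v <- get(nm)
    if (nrow(v) > 0 && anyDuplicated(paste(v$chrom, v$pos)))
      stop("duplicate positions within the ", nm, " set")
  }
  key <- function(v) {
    k <- paste(v$chrom, v$pos, v$alt, sep = ":")
    if (match_on_genotype) k <- paste(k, v$genotype, sep = ":")
    k
  }
  kt <- key(truth); kc <- key(called)
  tp <- called[kc %in% kt, , drop = FALSE]
  fp <- called[!kc %in% kt, , drop = FALSE]
  fn <- truth[!kt %in% kc, , drop = FALSE]
  conc <- NA_real_
  if (nrow(tp) > 0 && "genotype" %in% names(truth) &&
      "genotype" %in% names(called)) {
    kmatch <- paste(truth$chrom, truth$pos, truth$alt, sep = ":")
    idx <- match(paste(tp$chrom, tp$pos, tp$alt, sep = ":"), kmatch)
    conc <- mean(tp$genotype == truth$genotype[idx], na.rm = TRUE)
  }
  rownames(tp) <- rownames(fp) <- rownames(fn) <- NULL
  list(tp = tp, fp = fp, fn = fn, genotype_concordance = conc)
}

#' Accuracy, false-positive and false-negative rates
#'
#' \code{accuracy = TP / (TP + FP)} (percent of true positives among
#' called), \code{fp_rate = FP / (TP + FP)}, \code{fn_rate = FN /
#' (TP + FN)} (percent of missed variants among truth). With an empty
#' called set, accuracy and fp_rate are undefined and reported as
#' \code{NA}, never 0.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector \code{accuracy}, \code{fp_rate},
#'   \code{fn_rate}.
#' @export
compute_rates <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  called <- tp + fp
  truth <- tp + fn
  c(accuracy = if (called > 0) tp / called else NA_real_,
    fp_rate = if (called > 0) fp / called else NA_real_,
    fn_rate = if (truth > 0) fn / truth else NA_real_)
}

#' Stratified evaluation of one call set
#'
#' Classifies calls against truth globally, then stratifies records by the
#' stratum containing their position (calls outside every stratum fall into
#' \code{"other"} — these arise from mis-mapped reads and are not silently
#' dropped).
#'
#' @param truth,called Variant data frames.
#' @param strata Named list of \code{GRanges} (e.g. from
#'   [define_strata()]).
#' @param match_on_genotype Passed to [classify_calls()].
#' @return Data frame with one row per stratum: \code{stratum}, \code{TP},
#'   \code{FP}, \code{FN}, \code{accuracy}, \code{fp_rate}, \code{fn_rate},
#'   \code{genotype_concordance}.
#' @export
evaluate_calls <- function(truth, called, strata,
                           match_on_genotype = FALSE) {
  cls <- classify_calls(truth, called, match_on_genotype)
  strat <- function(v) stratum_of(v$chrom, v$pos, strata)
  labels <- c(names(strata), "other")
  tp_s <- factor(strat(cls$tp), levels = labels)
  fp_s <- factor(strat(cls$fp), levels = labels)
  fn_s <- factor(strat(cls$fn), levels = labels)
  out <- do.call(rbind, lapply(labels, function(l) {
    tp <- sum(tp_s == l); fp <- sum(fp_s == l); fn <- sum(fn_s == l)
    r <- compute_rates(tp, fp, fn)
    data.frame(stratum = l, TP = tp, FP = fp, FN = fn,
               accuracy = r[["accuracy"]], fp_rate = r[["fp_rate"]],
               fn_rate = r[["fn_rate"]], stringsAsFactors = FALSE)
  }))
  # drop the catch-all row when nothing landed there
  if (out$TP[out$stratum == "other"] + out$FP[out$stratum == "other"] +
      out$FN[out$stratum == "other"] == 0)
    out <- out[out$stratum != "other", , drop = FALSE]
  out$genotype_concordance <- cls$genotype_concordance
  rownames(out) <- NULL
  out
}

#' All-to-all t-tests between sequencing strategies
#'
#' Pooled-variance two-sample t-tests ("independent samples t-test") on a
#' per-replicate metric, for every unordered pair of strategies.
#'
#' @param report Data frame with columns \code{strategy}, \code{replicate}
#'   and the metric (e.g. the per-replicate \code{accuracy}).
#' @param metric Metric column name (default \code{"accuracy"}).
#' @param alpha Significance threshold used for the star matrix (default
#'   1e-4).
#' @return List of symmetric matrices \code{t}, \code{p} and logical
#'   \code{significant}; strategies in the row/column order of first
#'   appearance. When both groups have zero variance and equal means, p = 1
#'   by convention.
#' @export
compare_strategies_ttest <- function(report, metric = "accuracy",
                                     alpha = 1e-4) {
  if (!metric %in% names(report)) stop("no metric column '", metric, "'")
  strategies <- unique(report$strategy)
  k <- length(strategies)
  tm <- matrix(NA_real_, k, k, dimnames = list(strategies, strategies))
  pm <- tm
  vals <- lapply(strategies, function(s)
    report[[metric]][report$strategy == s & !is.na(report[[metric]])])
  nrep <- vapply(vals, length, integer(1))
  if (any(nrep < 2)) stop("at least 2 replicates per strategy are required")
  for (i in seq_len(k)) {
    pm[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- vals[[i]]; y <- vals[[j]]
      if (stats::var(x) == 0 && stats::var(y) == 0) {
        tm[i, j] <- tm[j, i] <- if (mean(x) == mean(y)) 0 else Inf
        pm[i, j] <- pm[j, i] <- if (mean(x) == mean(y)) 1 else 0
      } else {
        tt <- t.test(x, y, var.equal = TRUE)
        tm[i, j] <- tm[j, i] <- unname(tt$statistic)
        pm[i, j] <- pm[j, i] <- tt$p.value
      }
    }
  }
  list(t = tm, p = pm, significant = pm < alpha, alpha = alpha,
       metric = metric)
}

#' Sample matched random regions
#'
#' Draws a random region set with the same cardinality and the same
#' multiset of lengths as the template: chromosome chosen with probability
#' proportional to chromosome length, start uniform given the chromosome,
#' regions non-overlapping and within bounds, by bounded rejection
#' sampling (longest regions placed first).
#'
#' @param template \code{GRanges} whose length distribution to match.
#' @param genome An \code{mcr_genome}.
#' @param seed Integer seed (\code{NULL} to use the current RNG stream).
#' @param max_retries Rejection retries per region before failing.
#' @return \code{GRanges} of matched random regions.
#' @export
sample_matched_regions <- function(template, genome, seed = NULL,
                                   max_retries = 1000L) {
  validate_intervals(template, genome)
  lens <- sort(GenomicRanges::width(template), decreasing = TRUE)
  chrn <- names(genome$seq)
  clen <- as.numeric(genome$lengths)
  prob <- clen / sum(clen)
  with_seed(seed, {
    placed_start <- integer(0); placed_end <- integer(0)
    placed_chrom <- character(0)
    for (len in lens) {
      ok <- FALSE
      for (r in seq_len(max_retries)) {
        ci <- sample.int(length(chrn), 1L, prob = prob)
        L <- clen[ci]
        if (L < len) next
        s <- 1L + floor(runif(1) * (L - len + 1))
        e <- s + len - 1L
        same <- placed_chrom == chrn[ci]
        if (!any(same & placed_start <= e & placed_end >= s)) {
          placed_chrom <- c(placed_chrom, chrn[ci])
          placed_start <- c(placed_start, as.integer(s))
          placed_end <- c(placed_end, as.integer(e))
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("placement error: could not place a ", len,
                    " bp region after ", max_retries, " retries")
    }
    GenomicRanges::GRanges(placed_chrom,
                           IRanges::IRanges(placed_start, placed_end))
  })
}

# Pearson chi-squared for a 2x2 table, no continuity correction:
# n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
chisq2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (den == 0) return(c(stat = NA_real_, p = NA_real_))
  stat <- n * (a * d - b * c)^2 / den
  c(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Matched-random-region enrichment test
#'
#' Counts how many query intervals overlap at least one feature, then
#' repeats the count for \code{n_sims} matched random region sets drawn by
#' [sample_matched_regions()]. Each simulation yields a 2x2 chi-squared
#' statistic of (overlap, non-overlap) x (real, shuffled); the headline
#' p-value is the empirical two-sided permutation p,
#' \code{2 * min(r, 1 - r)} with \code{r = (1 + #\{sims >= observed\}) /
#' (n_sims + 1)}, capped at 1.
#'
#' @param query \code{GRanges} of query intervals (e.g. MCRs).
#' @param features \code{GRanges} of feature intervals.
#' @param genome An \code{mcr_genome}.
#' @param n_sims Number of matched shuffles (default 1000; fewer than 100
#'   triggers a warning about p-value stability).
#' @param seed Integer seed.
#' @return An \code{mcr_enrichment} list: \code{observed},
#'   \code{shuffled} (integer vector), \code{chisq} and \code{p_per_sim},
#'   \code{pooled_chisq}, \code{pooled_p}, \code{p_empirical},
#'   \code{direction} (\code{"over"}, \code{"under"} or \code{NA} when
#'   saturated), \code{n_query}, \code{n_sims}.
#' @export
enrichment_test <- function(query, features, genome, n_sims = 1000L,
                            seed = 1L) {
  validate_intervals(query, genome)
  validate_intervals(features, genome)
  if (n_sims < 100) warning("n_sims < 100: empirical p-value is unstable")
  nq <- length(query)
  if (nq == 0) stop("empty query set")
  observed <- sum(IRanges::overlapsAny(query, features,
                                       ignore.strand = TRUE))
  with_seed(seed, {
    shuffled <- integer(n_sims)
    stat <- numeric(n_sims); pval <- numeric(n_sims)
    for (i in seq_len(n_sims)) {
      rnd <- sample_matched_regions(query, genome, seed = NULL)
      shuffled[i] <- sum(IRanges::overlapsAny(rnd, features,
                                              ignore.strand = TRUE))
      cs <- chisq2x2(observed, nq - observed, shuffled[i], nq - shuffled[i])
      stat[i] <- cs[["stat"]]; pval[i] <- cs[["p"]]
    }
    pooled <- chisq2x2(observed, nq - observed,
                       sum(shuffled), n_sims * nq - sum(shuffled))
    r_ge <- (1 + sum(shuffled >= observed)) / (n_sims + 1)
    r_le <- (1 + sum(shuffled <= observed)) / (n_sims + 1)
    p_emp <- min(1, 2 * min(r_ge, r_le))
    msh <- mean(shuffled)
    direction <- if (observed == nq && all(shuffled == nq)) NA_character_
      else if (observed > msh) "over"
      else if (observed < msh) "under" else NA_character_
    structure(list(observed = observed, shuffled = shuffled,
                   chisq = stat, p_per_sim = pval,
                   pooled_chisq = pooled[["stat"]],
                   pooled_p = pooled[["p"]],
                   p_empirical = p_emp, direction = direction,
                   n_query = nq, n_sims = as.integer(n_sims)),
              class = "mcr_enrichment")
  })
}

#' @export
print.mcr_enrichment <- function(x, ...) {
  cat("<mcr_enrichment> ", x$observed, "/", x$n_query,
      " query intervals overlap features; shuffled mean ",
      sprintf("%.2f", mean(x$shuffled)), " (", x$n_sims, " sims)\n",
      "  empirical two-sided p = ", format(x$p_empirical, digits = 3),
      if (!is.na(x$direction)) paste0(" (", x$direction, "-represented)"),
      "\n", sep = "")
  invisible(x)
}
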