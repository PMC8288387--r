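#' Five-state genomic composition summary
#'
#' Proportions of the five homoeolog dosage states (NPB:93-11 = 4:0, 3:1,
#' 2:2, 1:3, 0:4) over all called individual x bin cells, genome-wide, per
#' chromosome and per cross direction, plus the parental genomic shares
#' (NPB share = mean(d)/4).
#'
#' @param dm a [dosage_matrix()].
#' @return object of class `composition_summary`: list with `genome` (named
#'   proportions in state order 4:0 .. 0:4), `npb_share`, `ind_share`,
#'   `per_chromosome` and `per_cross` data.frames.
#' @export
composition_summary <- function(dm) {
  if (all(is.na(dm$d))) stop("no called bins")
  states <- c("4:0", "3:1", "2:2", "1:3", "0:4")
  prop5 <- function(x) {
    x <- x[!is.na(x)]
    stats::setNames(tabulate(5L - x, nbins = 5) / length(x), states)
  }
  per_chr <- do.call(rbind, lapply(seq_len(nrow(dm$grid$chromosomes)), function(ci) {
    ch <- dm$grid$chromosomes[ci, ]
    cols <- ch$offset + seq_len(ch$n_bins)
    x <- dm$d[, cols]
    data.frame(chrom = ch$chrom, t(prop5(x)),
               npb_share = mean(x, na.rm = TRUE) / 4, check.names = FALSE)
  }))
  per_cross <- NULL
  if (!is.null(dm$samples$cross)) {
    per_cross <- do.call(rbind, lapply(unique(dm$samples$cross), function(cr) {
      x <- dm$d[dm$samples$cross == cr, , drop = FALSE]
      data.frame(cross = cr, t(prop5(x)),
                 npb_share = mean(x, na.rm = TRUE) / 4, check.names = FALSE)
    }))
  }
  npb <- mean(dm$d, na.rm = TRUE) / 4
  structure(list(genome = prop5(dm$d), npb_share = npb, ind_share = 1 - npb,
                 per_chromosome = per_chr, per_cross = per_cross),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("state proportions (NPB:93-11):\n")
  print(round(x$genome, 4))
  cat(sprintf("parental shares: NPB %.2f%%, 93-11 %.2f%%\n",
              100 * x$npb_share, 100 * x$ind_share))
  invisible(x)
}

#' Two-sided exact binomial symmetry test
#'
#' Tests two mirror-state counts (e.g. 4:0 vs 0:4 bins) against the null of a
#' 50:50 split, using the exact binomial test with the minimum-likelihood
#' two-sided convention (sum of outcome probabilities no larger than that of
#' the observation).
#'
#' @param count_a,count_b non-negative counts.
#' @return two-sided p-value.
#' @export
symmetry_test <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0) stop("counts must be >= 0")
  if (count_a + count_b < 1) stop("need at least one observation")
  stats::binom.test(count_a, count_a + count_b, p = 0.5)$p.value
}

.perm_p <- function(perm, obs, n_perm) {
  # two-sided empirical p with pseudocount; never zero
  lo <- sum(perm <= obs); hi <- sum(perm >= obs)
  min(1, (1 + 2 * min(lo, hi)) / (n_perm + 1))
}

#' Per-chromosome HE density with permutation Poisson test
#'
#' Compares the observed HE count per chromosome with a null in which the
#' genome-wide total is redistributed across chromosomes with probability
#' proportional to physical length.  Density is also expressed in
#' crossover-equivalent map units: `cM/Mb = 100 * (events per meiosis on the
#' chromosome) / length in Mb`.
#'
#' @param he an [he_events()] table.
#' @param grid a [genome_grid()].
#' @param n_meioses number of meioses represented by the event table
#'   (conventionally `2 * generations * individuals`).
#' @param n_perm number of permutations (>= 1000).
#' @param seed optional RNG seed.
#' @return data.frame: per chromosome `count`, `length_mb`, `per_mb`,
#'   `cm_per_mb`, `p` (two-sided empirical, +1 smoothed).
#' @export
chromosome_density_test <- function(he, grid, n_meioses, n_perm = 10000,
                                    seed = NULL) {
  stopifnot(n_perm >= 1000)
  if (!is.null(seed)) set.seed(seed)
  ch <- grid$chromosomes
  obs <- vapply(ch$chrom, function(c) sum(he$chrom == c), 0)
  total <- sum(obs)
  len_mb <- ch$length / 1e6
  out <- data.frame(chrom = ch$chrom, count = obs, length_mb = len_mb,
                    per_mb = obs / len_mb,
                    cm_per_mb = 100 * (obs / n_meioses) / len_mb,
                    p = 1, stringsAsFactors = FALSE)
  if (total == 0 || nrow(ch) < 2) return(out)
  prob <- ch$length / sum(ch$length)
  perm <- stats::rmultinom(n_perm, total, prob)   # chrom x n_perm
  out$p <- vapply(seq_len(nrow(ch)),
                  function(i) .perm_p(perm[i, ], obs[i], n_perm), 0)
  out
}

#' Pericentromeric / subtelomeric enrichment of HE breakpoints
#'
#' Classifies each breakpoint by the regional class of its boundary
#' ([region_classes()]) and compares observed class counts against uniform
#' placement of the same number of events along each chromosome.
#'
#' @param he an [he_events()] table.
#' @param grid a [genome_grid()].
#' @param n_perm number of permutations.
#' @param seed optional RNG seed.
#' @return data.frame per class: `observed`, `expected`, `oe_ratio`
#'   (NA when no events) and two-sided empirical `p`.
#' @export
regional_enrichment <- function(he, grid, n_perm = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- region_classes(grid)
  lev <- levels(cls)
  if (nrow(he) == 0)
    return(data.frame(class = lev, observed = 0, expected = NA_real_,
                      oe_ratio = NA_real_, p = NA_real_))
  bcls <- cls[bin_index(grid, he$chrom, he$boundary)]
  obs <- table(factor(bcls, levels = lev))
  ch <- grid$chromosomes
  n_by_chr <- vapply(ch$chrom, function(c) sum(he$chrom == c), 0)
  # class length fraction per chromosome -> expected under uniform placement
  frac <- vapply(seq_len(nrow(ch)), function(ci) {
    cols <- ch$offset[ci] + seq_len(ch$n_bins[ci])
    tabulate(cls[cols], nbins = 3) / ch$n_bins[ci]
  }, numeric(3))
  expected <- as.vector(frac %*% n_by_chr)
  perm <- matrix(0L, 3, n_perm)
  for (ci in which(n_by_chr > 0)) {
    draws <- stats::rmultinom(n_perm, n_by_chr[ci], frac[, ci])
    perm <- perm + draws
  }
  p <- vapply(1:3, function(k) .perm_p(perm[k, ], obs[k], n_perm), 0)
  data.frame(class = lev, observed = as.vector(obs), expected = expected,
             oe_ratio = ifelse(expected > 0, as.vector(obs) / expected, NA),
             p = p, stringsAsFactors = FALSE)
}
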