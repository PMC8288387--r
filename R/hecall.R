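#' Pooled per-bin dosage likelihoods
#'
#' Pools the parental allele depths of all SNPs in each 5-kb bin and scores
#' the five dosage states d in {0..4} under a binomial read model: with K NPB
#' reads of N total, `loglik(d) = K log f_d + (N - K) log(1 - f_d)` where
#' `f_d = (d/4)(1 - 2e) + e` and e is the per-read error rate.  Bins with no
#' reads are flagged missing.  The pooled counts (a sufficient statistic) are
#' stored; log-likelihoods are materialised on demand.
#'
#' @param adm an [allele_depth_matrix()].
#' @param grid a [genome_grid()].
#' @param error_rate per-read misassignment probability e, `0 <= e < 0.5`.
#'   With `e = 0`, impossible configurations (0 < K < N under d = 0 or 4)
#'   score a large negative number rather than -Inf/NaN.
#' @return object of class `bin_likelihoods`: pooled `K` and `N` integer
#'   matrices (individuals x bins), `e`, `grid`, and per-bin SNP counts.
#' @export
bin_likelihoods <- function(adm, grid, error_rate = 0.01) {
  stopifnot(error_rate >= 0, error_rate < 0.5)
  sbin <- bin_index(grid, adm$panel$chrom, adm$panel$pos)
  group <- factor(sbin, levels = seq_len(grid$n_bins_total))
  K <- t(rowsum(t(adm$npb), group))      # individuals x bins
  N <- K + t(rowsum(t(adm$ind), group))
  storage.mode(K) <- "integer"; storage.mode(N) <- "integer"
  structure(list(K = K, N = N, e = error_rate, grid = grid,
                 snps_per_bin = tabulate(sbin, grid$n_bins_total)),
            class = "bin_likelihoods")
}

#' @export
print.bin_likelihoods <- function(x, ...) {
  cat(sprintf("bin_likelihoods: %d individuals x %d bins, e = %g, %.1f%% bins informative\n",
              nrow(x$K), ncol(x$K), x$e, 100 * mean(x$N > 0)))
  invisible(x)
}

## log-likelihood matrices for one chromosome slice; list of 5 (ind x nb)
.emission_ll <- function(bl, cols) {
  f <- (0:4) / 4 * (1 - 2 * bl$e) + bl$e
  K <- bl$K[, cols, drop = FALSE]; N <- bl$N[, cols, drop = FALSE]
  lapply(1:5, function(s) {
    ll <- K * max(log(f[s]), -1e10) + (N - K) * max(log(1 - f[s]), -1e10)
    ll[N == 0L] <- 0
    ll
  })
}

#' Per-bin maximum-likelihood dosage (no smoothing)
#'
#' @param bl a [bin_likelihoods()] object.
#' @return integer matrix of argmax dosage states, NA where no reads.
#' @export
ml_dosage <- function(bl) {
  out <- matrix(NA_integer_, nrow(bl$K), ncol(bl$K),
                dimnames = dimnames(bl$K))
  for (i in seq_len(nrow(bl$grid$chromosomes))) {
    ch <- bl$grid$chromosomes[i, ]
    cols <- ch$offset + seq_len(ch$n_bins)
    ll <- .emission_ll(bl, cols)
    best <- matrix(1L, nrow(bl$K), length(cols))
    cur <- ll[[1]]
    for (s in 2:5) {
      upd <- ll[[s]] > cur
      best[upd] <- s
      cur[upd] <- ll[[s]][upd]
    }
    best[bl$N[, cols, drop = FALSE] == 0L] <- NA_integer_
    out[, cols] <- best - 1L
  }
  out
}

## Core DP: ll5 is a list of 5 emission log-likelihood matrices (n x nb);
## returns the most probable state path per row (n x nb, states 1..5).
.viterbi_core <- function(ll5, l_stay, l_sw) {
  n <- nrow(ll5[[1]]); nb <- ncol(ll5[[1]])
  delta <- vapply(1:5, function(s) ll5[[s]][, 1], numeric(n))
  if (n == 1) delta <- matrix(delta, 1, 5)
  ptr <- array(0L, c(n, nb, 5))
  if (nb >= 2) {
    for (t in 2:nb) {
      i1 <- max.col(delta, ties.method = "first")
      m1 <- delta[cbind(seq_len(n), i1)]
      d2 <- delta; d2[cbind(seq_len(n), i1)] <- -Inf
      i2 <- max.col(d2, ties.method = "first")
      m2 <- d2[cbind(seq_len(n), i2)]
      for (s in 1:5) {
        other_m <- ifelse(i1 == s, m2, m1)
        other_i <- ifelse(i1 == s, i2, i1)
        stay <- delta[, s] + l_stay
        swit <- other_m + l_sw
        take_stay <- stay >= swit          # tie -> extend the run
        ptr[, t, s] <- ifelse(take_stay, s, other_i)
        delta[, s] <- ifelse(take_stay, stay, swit) + ll5[[s]][, t]
      }
    }
  }
  path <- matrix(0L, n, nb)
  path[, nb] <- max.col(delta, ties.method = "first")
  if (nb >= 2) for (t in nb:2) path[, t - 1L] <- ptr[cbind(seq_len(n), t, path[, t])]
  path
}

## single-sequence convenience used by tests: ll is nb x 5, returns 0-based path
.viterbi_ll <- function(ll, switch_prob) {
  ll5 <- lapply(1:5, function(s) matrix(ll[, s], 1))
  .viterbi_core(ll5, log(1 - switch_prob), log(switch_prob / 4))[1, ] - 1L
}

#' Viterbi smoothing of dosage states along chromosomes
#'
#' Finds, per individual and chromosome, the most probable five-state dosage
#' path under a left-to-right Markov chain: staying in a state has log
#' probability `log(1 - tau)` per bin boundary, switching to any of the four
#' other states `log(tau / 4)`.  Bins without reads contribute a flat
#' emission and are assigned the smoothed state.  Ties are broken toward the
#' left-neighbour state (runs extend rather than switch).
#'
#' @param bl a [bin_likelihoods()] object.
#' @param switch_prob per-boundary switch probability tau, `0 < tau < 1`
#'   (default 1e-4).
#' @param samples optional sample metadata passed to [dosage_matrix()].
#' @return a [dosage_matrix()] of smoothed states.  Chromosomes with no
#'   informative bin for an individual are returned all-NA with a warning.
#' @export
viterbi_dosage <- function(bl, switch_prob = 1e-4, samples = NULL) {
  stopifnot(switch_prob > 0, switch_prob < 1)
  l_stay <- log(1 - switch_prob)
  l_sw <- log(switch_prob / 4)
  n <- nrow(bl$K)
  out <- matrix(NA_integer_, n, ncol(bl$K), dimnames = dimnames(bl$K))
  warned <- FALSE
  for (ci in seq_len(nrow(bl$grid$chromosomes))) {
    ch <- bl$grid$chromosomes[ci, ]
    cols <- ch$offset + seq_len(ch$n_bins)
    nb <- ch$n_bins
    ll <- .emission_ll(bl, cols)
    empty <- rowSums(bl$N[, cols, drop = FALSE] > 0L) == 0L
    if (any(empty) && !warned) {
      warning("individual(s) with no informative bins on ", ch$chrom,
              "; path set to NA")
      warned <- TRUE
    }
    path <- .viterbi_core(ll, l_stay, l_sw) - 1L
    path[empty, ] <- NA_integer_
    out[, cols] <- path
  }
  dosage_matrix(out, bl$grid, samples)
}

#' Call HE breakpoints from a dosage matrix
#'
#' One event per change of state between adjacent called bins; the boundary
#' is their shared edge.  A state change across a run of uncalled (NA) bins
#' is bridged: one event at the boundary nearest the midpoint of the gap,
#' flagged `low_resolution`.
#'
#' @param dm a [dosage_matrix()] (typically smoothed).
#' @return an [he_events()] table.
#' @export
call_breakpoints <- function(dm) {
  bins <- dm$bins
  res <- vector("list", 256); nres <- 0L
  for (ci in seq_len(nrow(dm$grid$chromosomes))) {
    ch <- dm$grid$chromosomes[ci, ]
    cols <- ch$offset + seq_len(ch$n_bins)
    for (i in seq_len(nrow(dm$d))) {
      s <- dm$d[i, cols]
      ok <- which(!is.na(s))
      if (length(ok) < 2) next
      chg <- which(s[ok[-1]] != s[ok[-length(ok)]])
      if (!length(chg)) next
      left <- ok[chg]; right <- ok[chg + 1L]
      bnd_local <- ifelse(right - left == 1L, left, floor((left + right) / 2))
      nres <- nres + 1L
      res[[nres]] <- data.frame(
        individual = rownames(dm$d)[i], chrom = ch$chrom,
        boundary = bins$start[ch$offset + bnd_local + 1L],
        left_state = s[left], right_state = s[right],
        low_resolution = right - left > 1L, stringsAsFactors = FALSE)
    }
  }
  if (nres == 0L) return(he_events())
  ev <- do.call(rbind, res[seq_len(nres)])
  rownames(ev) <- NULL
  class(ev) <- c("he_events", "data.frame")
  ev
}

#' Depth-based euploidy screen
#'
#' Flags individuals whose per-chromosome median bin depth, normalised by
#' their genome-wide median bin depth, deviates from 1 by more than
#' `tolerance` on any chromosome (a whole-chromosome gain of one copy shifts
#' the ratio to about 1.25, a loss to 0.75).
#'
#' @param adm an [allele_depth_matrix()].
#' @param grid a [genome_grid()].
#' @param tolerance allowed deviation of the normalised depth from 1
#'   (default 0.15, the midpoint between euploid and a one-copy gain).
#' @return data.frame: `individual`, `verdict` (`"euploid"`/`"aneuploid"`),
#'   `worst_chrom`, `worst_ratio`.
#' @export
screen_euploidy <- function(adm, grid, tolerance = 0.15) {
  stopifnot(tolerance > 0)
  sbin <- bin_index(grid, adm$panel$chrom, adm$panel$pos)
  group <- factor(sbin, levels = seq_len(grid$n_bins_total))
  tot <- t(rowsum(t(adm$npb + adm$ind), group))   # ind x bins
  n <- nrow(tot)
  ch <- grid$chromosomes
  ratios <- matrix(NA_real_, n, nrow(ch))
  gmed <- apply(tot, 1, stats::median)
  if (any(gmed == 0)) stop("genome-wide median bin depth is zero")
  for (ci in seq_len(nrow(ch))) {
    cols <- ch$offset[ci] + seq_len(ch$n_bins[ci])
    ratios[, ci] <- apply(tot[, cols, drop = FALSE], 1, stats::median) / gmed
  }
  dev <- abs(ratios - 1)
  worst <- max.col(dev, ties.method = "first")
  data.frame(individual = rownames(adm$npb),
             verdict = ifelse(apply(dev, 1, max) > tolerance,
                              "aneuploid", "euploid"),
             worst_chrom = ch$chrom[worst],
             worst_ratio = ratios[cbind(seq_len(n), worst)],
             stringsAsFactors = FALSE)
}

#' Per-meiosis and per-chromosome-pair HE rates
#'
#' A selfing pedigree accrues two meioses per generation (one per gamete), so
#' the per-meiosis rate is the mean per-individual cumulative HE count
#' divided by `2 g`; the per-pair rate divides further by the number of
#' homoeologous chromosome pairs (24 for tetraploid rice).
#'
#' @param counts per-individual cumulative HE counts (numeric vector), or an
#'   [he_events()] table combined with `individuals` giving the full roster
#'   (individuals without events count zero).
#' @param generations number of selfing generations g.
#' @param n_pairs homoeologous chromosome pairs (default 24).
#' @param individuals roster used when `counts` is an event table.
#' @return list with `per_meiosis` and `per_pair`.
#' @export
he_rate <- function(counts, generations, n_pairs = 24, individuals = NULL) {
  stopifnot(generations >= 1)
  if (is.data.frame(counts)) {
    if (is.null(individuals)) individuals <- unique(counts$individual)
    counts <- vapply(individuals,
                     function(id) sum(counts$individual == id), 0)
  }
  if (length(counts) == 0 || sum(counts) == 0)
    return(list(per_meiosis = 0, per_pair = 0))
  pm <- mean(counts) / (2 * generations)
  list(per_meiosis = pm, per_pair = pm / n_pairs)
}
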