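#' Encode homoeolog dosage for GWAS
#'
#' Maps the five dosage states, in the order NPB:93-11 = 0:4, 1:3, 2:2, 3:1,
#' 4:0 (i.e. d = 0..4), to numeric marker codes:
#' * `additive`: 0, 1, 2, 3, 4
#' * `dom_i`   : 0, 1, 1, 1, 0 (heterozygote vs either homozygote)
#' * `dom_ii`  : 0, 2, 2, 2, 1 (transgressive NPB homozygote)
#' * `dom_iii` : 1, 2, 2, 2, 0 (transgressive 93-11 homozygote)
#'
#' @param dm a [dosage_matrix()].
#' @param model one of `"additive"`, `"dom_i"`, `"dom_ii"`, `"dom_iii"`.
#' @return object of class `encoded_genotypes`: numeric matrix (individuals x
#'   bins, NA propagated) with attributes `model` and `bins`.
#' @export
encode_dosage <- function(dm, model = c("additive", "dom_i", "dom_ii", "dom_iii")) {
  model <- match.arg(model)
  codes <- switch(model,
                  additive = c(0, 1, 2, 3, 4),
                  dom_i = c(0, 1, 1, 1, 0),
                  dom_ii = c(0, 2, 2, 2, 1),
                  dom_iii = c(1, 2, 2, 2, 0))
  m <- matrix(codes[dm$d + 1L], nrow(dm$d), ncol(dm$d),
              dimnames = dimnames(dm$d))
  structure(m, model = model, bins = dm$bins, class = c("encoded_genotypes", "matrix"))
}

#' Bonferroni family-wise threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests M (>= 1).
#' @return per-test threshold `alpha / M`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

## OLS of y on [1, C, m]; returns effect, se, p of m via the QR decomposition.
.marker_ols <- function(y, m, C = NULL) {
  X <- cbind(1, C, m)
  XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  if (is.null(XtXinv) && !is.null(C)) {
    warning("rank-deficient design; pseudo-QTN covariates dropped for one test")
    X <- cbind(1, m)
    XtXinv <- tryCatch(chol2inv(chol(crossprod(X))), error = function(e) NULL)
  }
  if (is.null(XtXinv)) return(c(NA_real_, NA_real_, NA_real_))
  n <- length(y); p <- ncol(X)
  if (n <= p) return(c(NA_real_, NA_real_, NA_real_))
  beta <- XtXinv %*% crossprod(X, y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (n - p)
  se <- sqrt(s2 * XtXinv[p, p])
  b <- beta[p]
  if (se == 0 || !is.finite(se)) {
    pv <- if (abs(b) > 1e-12) 0 else 1
    return(c(b, se, pv))
  }
  tv <- b / se
  c(b, se, 2 * stats::pt(abs(tv), n - p, lower.tail = FALSE))
}

#' Iterative fixed-effect dosage GWAS with pseudo-QTN covariates
#'
#' FarmCPU-style iteration adapted to a single biparental selfing family
#' (no population structure, hence no random-effect step): (1) each marker is
#' tested by OLS of the trait on its code with the current pseudo-QTN codes
#' as fixed covariates, dropping for that test any pseudo-QTN correlated with
#' the marker at |r| > `r_prune`; (2) markers passing the Bonferroni
#' threshold are greedily selected as the new pseudo-QTN set in order of
#' significance, subject to mutual |r| <= `r_prune`; (3) repeat until the set
#' is unchanged or `max_iter`.  Iteration 1 (empty pseudo-QTN set) is plain
#' single-marker OLS.
#'
#' @param eg an [encode_dosage()] matrix (individuals x markers).
#' @param tt a trait table.
#' @param trait trait column name.
#' @param alpha family-wise alpha for [bonferroni_threshold()] (default 0.05).
#' @param max_iter maximum iterations (default 10).
#' @param r_prune correlation cutoff for covariate/test exclusion and
#'   pseudo-QTN mutual pruning (default 0.7).
#' @return object of class `gwas_result`: list with `scan` (per-marker
#'   data.frame: `marker`, `chrom`, `start`, `end`, `effect`, `se`, `p`),
#'   `threshold`, `n_tests`, `signals` (the pruned pseudo-QTN peaks passing
#'   the threshold), `converged`, `n_iter`, `trait`, `model`.
#' @export
run_gwas <- function(eg, tt, trait, alpha = 0.05, max_iter = 10, r_prune = 0.7) {
  ids <- intersect(rownames(eg), tt$individual)
  if (length(ids) < 30) stop("need >= 30 individuals with genotype and trait")
  y <- tt[[trait]][match(ids, tt$individual)]
  G <- eg[ids, , drop = FALSE]
  ok <- !is.na(y) & rowSums(is.na(G)) == 0
  y <- y[ok]; G <- G[ok, , drop = FALSE]
  v <- apply(G, 2, stats::var)
  testable <- which(v > 0)
  M <- length(testable)
  if (M < 1) stop("no polymorphic markers")
  thr <- bonferroni_threshold(alpha, M)
  qtn <- integer(0)
  scan <- NULL
  converged <- FALSE
  history <- list()
  for (iter in seq_len(max_iter)) {
    Cmat <- if (length(qtn)) G[, qtn, drop = FALSE] else NULL
    rq <- if (length(qtn)) suppressWarnings(stats::cor(G[, testable, drop = FALSE],
                                                       Cmat)) else NULL
    res <- matrix(NA_real_, length(testable), 3)
    for (jj in seq_along(testable)) {
      j <- testable[jj]
      C <- Cmat
      if (!is.null(C)) {
        drop <- which(abs(rq[jj, ]) > r_prune | is.na(rq[jj, ]))
        if (length(drop)) C <- C[, -drop, drop = FALSE]
        if (!is.null(C) && ncol(C) == 0) C <- NULL
      }
      res[jj, ] <- .marker_ols(y, G[, j], C)
    }
    scan <- res
    sig <- testable[which(res[, 3] < thr)]
    sig <- sig[order(res[match(sig, testable), 3])]
    new_qtn <- integer(0)
    for (j in sig) {
      if (!length(new_qtn) ||
          all(abs(suppressWarnings(stats::cor(G[, j], G[, new_qtn]))) <= r_prune,
              na.rm = TRUE))
        new_qtn <- c(new_qtn, j)
    }
    key <- paste(sort(new_qtn), collapse = ",")
    if (identical(sort(new_qtn), sort(qtn)) || key %in% unlist(history)) {
      # stationary, or revisiting an earlier set (oscillation between
      # equivalent taggings of one linkage block): stop here
      converged <- TRUE
      qtn <- new_qtn
      break
    }
    history[[iter]] <- key
    qtn <- new_qtn
  }
  bins <- attr(eg, "bins")
  full <- data.frame(marker = seq_len(ncol(eg)),
                     chrom = bins$chrom, start = bins$start, end = bins$end,
                     effect = NA_real_, se = NA_real_, p = NA_real_,
                     stringsAsFactors = FALSE)
  full$effect[testable] <- scan[, 1]
  full$se[testable] <- scan[, 2]
  full$p[testable] <- scan[, 3]
  structure(list(scan = full, threshold = thr, n_tests = M,
                 signals = full[qtn, , drop = FALSE], converged = converged,
                 n_iter = iter, trait = trait, model = attr(eg, "model")),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result (%s, %s): %d markers, threshold %.4g, %d signal(s)%s\n",
              x$trait, x$model, x$n_tests, x$threshold, nrow(x$signals),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Delineate the linked segment around a GWAS peak
#'
#' Extends left and right from the peak bin while the Pearson correlation
#' between each bin's dosage vector and the peak's exceeds `r_min`, stopping
#' at the first failure per side (and at chromosome edges).
#'
#' @param dm a [dosage_matrix()].
#' @param peak_bin global bin index of the peak.
#' @param r_min correlation cutoff (default 0.9, i.e. r > 0.9 is linked).
#' @return list with `chrom`, `start`, `end` (bp, half-open), `first_bin`,
#'   `last_bin`.
#' @export
delineate_segment <- function(dm, peak_bin, r_min = 0.9) {
  v <- dm$d[, peak_bin]
  if (stats::var(v, na.rm = TRUE) == 0 || all(is.na(v)))
    stop("peak bin has zero dosage variance")
  ci <- match(dm$bins$chrom[peak_bin], dm$grid$chromosomes$chrom)
  lo_lim <- dm$grid$chromosomes$offset[ci] + 1L
  hi_lim <- dm$grid$chromosomes$offset[ci] + dm$grid$chromosomes$n_bins[ci]
  linked <- function(j) {
    r <- suppressWarnings(stats::cor(v, dm$d[, j], use = "complete.obs"))
    !is.na(r) && r > r_min
  }
  lo <- peak_bin
  while (lo > lo_lim && linked(lo - 1L)) lo <- lo - 1L
  hi <- peak_bin
  while (hi < hi_lim && linked(hi + 1L)) hi <- hi + 1L
  list(chrom = dm$bins$chrom[peak_bin], start = dm$bins$start[lo],
       end = dm$bins$end[hi], first_bin = lo, last_bin = hi)
}

#' Genes overlapping delineated segments
#'
#' Half-open interval intersection: a gene abutting a segment boundary is not
#' reported.
#'
#' @param segments data.frame with `chrom`, `start`, `end` (one row per
#'   segment).
#' @param ann an [annotation_table()].
#' @return data.frame of genes per segment (zero rows when none overlap).
#' @export
annotate_candidates <- function(segments, ann) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    hit <- ann$chrom == segments$chrom[i] & ann$start < segments$end[i] &
      ann$end > segments$start[i]
    if (any(hit)) {
      g <- ann[hit, , drop = FALSE]
      g$segment_chrom <- segments$chrom[i]
      g$segment_start <- segments$start[i]
      g$segment_end <- segments$end[i]
      out[[length(out) + 1L]] <- as.data.frame(g)
    }
  }
  if (!length(out))
    return(data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
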