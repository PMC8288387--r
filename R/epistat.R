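#' Candidate locus pairs for epistasis testing
#'
#' All unordered pairs of a trait's GWAS signals, excluding pairs whose peaks
#' fall on the same delineated segment, ranked by joint significance
#' (ascending product of peak p-values) and capped at `max_pairs`.
#'
#' @param gwas a `gwas_result` from [run_gwas()].
#' @param dm the [dosage_matrix()] used for the scan (for segment
#'   delineation).
#' @param max_pairs cap on the number of pairs returned.
#' @param r_min segment delineation cutoff (see [delineate_segment()]).
#' @return data.frame with columns `bin_i`, `bin_j`, `p_i`, `p_j` (zero rows
#'   when fewer than two loci are available).
#' @export
pair_candidates <- function(gwas, dm, max_pairs = 500, r_min = 0.9) {
  sig <- gwas$signals
  empty <- data.frame(bin_i = integer(0), bin_j = integer(0),
                      p_i = numeric(0), p_j = numeric(0))
  if (nrow(sig) < 2) return(empty)
  segs <- lapply(sig$marker, function(b) delineate_segment(dm, b, r_min))
  out <- list()
  for (i in seq_len(nrow(sig) - 1)) {
    for (j in (i + 1):nrow(sig)) {
      same <- segs[[i]]$chrom == segs[[j]]$chrom &&
        segs[[i]]$first_bin <= segs[[j]]$last_bin &&
        segs[[j]]$first_bin <= segs[[i]]$last_bin
      if (same) next
      out[[length(out) + 1L]] <- data.frame(
        bin_i = sig$marker[i], bin_j = sig$marker[j],
        p_i = sig$p[i], p_j = sig$p[j])
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$p_i * res$p_j), , drop = FALSE]
  utils::head(res, max_pairs)
}

#' Two-locus F-infinity decomposition
#'
#' OLS of a trait on the F-infinity design
#' `[1, w1, v1, w2, v2, w1 w2, w1 v2, v1 w2, v1 v2]` with `w = (d - 2)/2`
#' and `v = [d in {1,2,3}]`, giving additive (a), dominance (d) and the four
#' interaction effects aa, ad, da, dd with per-coefficient t-tests.
#' Collinear terms (e.g. `v` at a locus segregating only 0/4) are dropped and
#' reported as NA.  When the fit is exact (zero residual variance) the
#' p-value is 0 for coefficients distinguishable from zero and 1 otherwise.
#'
#' @param y trait values.
#' @param d1,d2 NPB dosage vectors (0..4) at the two loci.
#' @param alpha per-coefficient significance level used by `sig_types`.
#' @return one-row data.frame with estimate/se/p for `mu`, `a1`, `d1`, `a2`,
#'   `d2`, `aa`, `ad`, `da`, `dd`, plus `sig_types` (comma-separated subset
#'   of AA, AD, DA, DD significant at `alpha`, unadjusted).
#' @export
f_infinity_fit <- function(y, d1, d2, alpha = 0.05) {
  ok <- !is.na(y) & !is.na(d1) & !is.na(d2)
  if (sum(ok) < 30) stop("need >= 30 complete observations")
  y <- y[ok]; d1 <- d1[ok]; d2 <- d2[ok]
  if (stats::var(d1) == 0 || stats::var(d2) == 0)
    stop("both loci must be polymorphic")
  c1 <- f_codes(d1); c2 <- f_codes(d2)
  X <- cbind(w1 = c1$w, v1 = c1$v, w2 = c2$w, v2 = c2$v,
             aa = c1$w * c2$w, ad = c1$w * c2$v, da = c1$v * c2$w,
             dd = c1$v * c2$v)
  fit <- stats::lm(y ~ X)
  sm <- suppressWarnings(summary(fit))   # sigma = 0 handled explicitly below
  cf <- stats::coef(fit)                       # NA for aliased terms
  tab <- sm$coefficients
  terms <- c("mu", "a1", "d1", "a2", "d2", "aa", "ad", "da", "dd")
  est <- se <- pv <- stats::setNames(rep(NA_real_, 9), terms)
  nm <- c("(Intercept)", paste0("X", colnames(X)))
  est[] <- cf[nm]
  present <- nm %in% rownames(tab)
  se[present] <- tab[nm[present], 2]
  pv[present] <- tab[nm[present], 4]
  if (sm$sigma^2 < 1e-16) {                    # exact fit: t-tests are 0/0
    pv[present] <- ifelse(abs(est[present]) > 1e-8, 0, 1)
  }
  inter <- c(aa = "AA", ad = "AD", da = "DA", dd = "DD")
  sig <- inter[names(inter)[!is.na(pv[names(inter)]) &
                              pv[names(inter)] < alpha]]
  out <- data.frame(t(est))
  names(out) <- terms
  for (t in terms) {
    out[[paste0("se_", t)]] <- se[[t]]
    out[[paste0("p_", t)]] <- pv[[t]]
  }
  out$sig_types <- paste(sig, collapse = ",")
  out$n <- length(y)
  out
}

#' F-infinity scan over candidate pairs
#'
#' Fits [f_infinity_fit()] for every pair, then applies a run-level BH
#' adjustment across all pairs x 4 interaction terms; a pair is flagged
#' epistatic if any interaction coefficient survives at `alpha`.
#'
#' @param dm a [dosage_matrix()].
#' @param tt a trait table.
#' @param trait trait column name.
#' @param pairs data.frame with `bin_i`, `bin_j` (see [pair_candidates()]).
#' @param alpha significance level after adjustment (default 0.05).
#' @return data.frame (class `epistasis_result`): per pair the coefficient
#'   table plus `adj_p_aa` .. `adj_p_dd`, `sig_types_adj` and `epistatic`.
#' @export
epistasis_scan <- function(dm, tt, trait, pairs, alpha = 0.05) {
  ids <- intersect(rownames(dm$d), tt$individual)
  y <- tt[[trait]][match(ids, tt$individual)]
  rows <- match(ids, rownames(dm$d))
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    r <- f_infinity_fit(y, dm$d[rows, pairs$bin_i[k]],
                        dm$d[rows, pairs$bin_j[k]], alpha)
    cbind(data.frame(trait = trait, bin_i = pairs$bin_i[k],
                     bin_j = pairs$bin_j[k]), r)
  }))
  pm <- as.matrix(res[, c("p_aa", "p_ad", "p_da", "p_dd")])
  adj <- matrix(stats::p.adjust(pm, method = "BH"), nrow(pm), 4,
                dimnames = list(NULL, c("adj_p_aa", "adj_p_ad", "adj_p_da",
                                        "adj_p_dd")))
  res <- cbind(res, adj)
  lab <- c("AA", "AD", "DA", "DD")
  res$sig_types_adj <- apply(adj, 1, function(p)
    paste(lab[!is.na(p) & p < alpha], collapse = ","))
  res$epistatic <- res$sig_types_adj != ""
  class(res) <- c("epistasis_result", "data.frame")
  res
}

#' Population summary of epistasis types
#'
#' Fraction of tested pairs flagged epistatic (per trait and overall) and the
#' frequency of each interaction type (a pair can count toward several
#' types), with a Pearson chi-square test of equal type frequencies.
#'
#' @param res an `epistasis_result` (rows from one or more traits).
#' @return list with `per_trait`, `type_freq` (per type: count and fraction
#'   of tested pairs), `chisq_types`, `p_types`, `n_pairs`,
#'   `fraction_epistatic`.
#' @export
epistasis_summary <- function(res) {
  if (nrow(res) == 0) stop("no tested pairs")
  lab <- c("AA", "AD", "DA", "DD")
  counts <- vapply(lab, function(l)
    sum(vapply(strsplit(res$sig_types_adj, ","), function(s) l %in% s, TRUE)), 0)
  per_trait <- do.call(rbind, lapply(unique(res$trait), function(tr) {
    s <- res[res$trait == tr, ]
    data.frame(trait = tr, n_pairs = nrow(s),
               fraction_epistatic = mean(s$epistatic), stringsAsFactors = FALSE)
  }))
  if (sum(counts) > 0) {
    e <- rep(sum(counts) / 4, 4)
    stat <- sum((counts - e)^2 / e)
    p <- stats::pchisq(stat, df = 3, lower.tail = FALSE)
  } else {
    stat <- 0; p <- 1
  }
  list(per_trait = per_trait,
       type_freq = data.frame(type = lab, count = counts,
                              fraction = counts / nrow(res)),
       chisq_types = stat, p_types = p, n_pairs = nrow(res),
       fraction_epistatic = mean(res$epistatic))
}
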