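#' Dosage-expression concordance test
#'
#' Per gene, individual and tissue, a Pearson goodness-of-fit test compares
#' the homoeolog transcript counts (K NPB of N) with the proportions expected
#' from the DNA dosage d of the gene's bin, `f_d = (d/4)(1 - 2e) + e` (the
#' small e keeps expectations away from zero at d = 0 or 4).  Per-individual
#' p-values are combined across individuals with Fisher's method; the
#' combined p is BH-adjusted across genes within a tissue.  A second
#' goodness-of-fit against the balanced null (always 1:1) guards against
#' calling concordance from low power alone: a gene is `dosage_dependent`
#' only if the dosage model is not rejected (adjusted p >= alpha) AND the
#' balanced null is rejected in at least one individual with d != 2;
#' `dosage_independent` if the dosage model is rejected; otherwise
#' `indeterminate`.
#'
#' @param ec expression counts (long data.frame from [sample_expression()] or
#'   with the same columns).
#' @param dm a [dosage_matrix()].
#' @param min_reads minimum transcript reads per gene x individual cell
#'   (default 20).
#' @param error_rate e used in the dosage expectations (default 0.001).
#' @param alpha significance level for the verdicts (default 0.05).
#' @return list (class `concordance_result`) with `cells` (per-cell GOF
#'   results) and `genes` (per gene x tissue: combined p, BH-adjusted p,
#'   balanced-null evidence, `verdict`).
#' @export
concordance_test <- function(ec, dm, min_reads = 20, error_rate = 0.001,
                             alpha = 0.05) {
  gbin <- bin_index(dm$grid, ec$chrom, ec$pos)
  i <- match(ec$individual, rownames(dm$d))
  if (anyNA(i)) stop("expression individuals missing from dosage matrix")
  d <- dm$d[cbind(i, gbin)]
  K <- ec$reads_npb; N <- ec$reads_npb + ec$reads_ind
  keep <- !is.na(d) & N >= min_reads
  f <- (d / 4) * (1 - 2 * error_rate) + error_rate
  gof <- function(p0) {
    ek <- N * p0
    stat <- (K - ek)^2 / ek + (K - ek)^2 / (N - ek)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  cells <- data.frame(gene = ec$gene, individual = ec$individual,
                      tissue = ec$tissue, dosage = d, reads_npb = K,
                      total = N, p_dosage = gof(f), p_balanced = gof(0.5),
                      tested = keep, stringsAsFactors = FALSE)
  tcells <- cells[keep, ]
  if (nrow(tcells) == 0) stop("no testable gene x individual cells")
  key <- interaction(tcells$gene, tcells$tissue, drop = TRUE)
  fisher <- function(p) {
    p <- pmax(p, 1e-300)
    stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
  }
  genes <- do.call(rbind, lapply(split(tcells, key), function(s) {
    data.frame(gene = s$gene[1], tissue = s$tissue[1], n_cells = nrow(s),
               p_dosage = fisher(s$p_dosage),
               balanced_rejected = any(s$dosage != 2 & s$p_balanced < alpha),
               n_informative = sum(s$dosage != 2), stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  genes$p_adj <- NA_real_
  for (ts in unique(genes$tissue)) {
    sel <- genes$tissue == ts
    genes$p_adj[sel] <- stats::p.adjust(genes$p_dosage[sel], method = "BH")
  }
  genes$verdict <- ifelse(genes$p_adj < alpha, "dosage_independent",
                          ifelse(genes$balanced_rejected, "dosage_dependent",
                                 "indeterminate"))
  structure(list(cells = cells, genes = genes, alpha = alpha),
            class = "concordance_result")
}

#' Fraction of dosage-dependent genes with Wilson interval
#'
#' @param conc a `concordance_result` from [concordance_test()].
#' @param conf confidence level of the Wilson score interval.
#' @return data.frame per tissue: `n_determinate`, `n_dependent`, `fraction`,
#'   `ci_lo`, `ci_hi` (fraction among genes with a determinate verdict).
#' @export
concordance_summary <- function(conc, conf = 0.95) {
  g <- conc$genes[conc$genes$verdict != "indeterminate", ]
  if (nrow(g) == 0) stop("no genes with a determinate verdict")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(unique(g$tissue), function(ts) {
    s <- g[g$tissue == ts, ]
    n <- nrow(s); x <- sum(s$verdict == "dosage_dependent")
    ph <- x / n
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    data.frame(tissue = ts, n_determinate = n, n_dependent = x,
               fraction = ph, ci_lo = max(0, ctr - hw),
               ci_hi = min(1, ctr + hw), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
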