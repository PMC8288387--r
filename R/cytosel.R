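#' Scan reciprocal crosses for biased homoeolog retention
#'
#' Per analysis bin and cross direction, computes the fraction of individuals
#' retaining at least one copy of the maternal homoeolog (NPB in NN99, 93-11
#' in 99NN) and likewise for the paternal homoeolog, and tests the bin's
#' five-state composition against the cross's genome-wide average state
#' frequencies with a Pearson chi-square goodness-of-fit test.  A bin is a
#' retention candidate in a direction if the retention fraction exceeds
#' `threshold` and the chi-square p-value is below `alpha`.
#'
#' @param dm a [dosage_matrix()] whose `samples$cross` labels both reciprocal
#'   crosses; at least 20 individuals per cross are required.
#' @param threshold retention fraction cutoff (default 0.95).
#' @param alpha chi-square significance level (default 0.01).
#' @return data.frame (class `retention_scan`) with one row per bin x cross:
#'   `bin`, `chrom`, `start`, `end`, `cross`, `frac_maternal`,
#'   `frac_paternal`, `chisq_p`, `maternal_candidate`, `paternal_candidate`.
#' @export
scan_retention <- function(dm, threshold = 0.95, alpha = 0.01) {
  crosses <- unique(dm$samples$cross)
  if (!all(c("NN99", "99NN") %in% crosses))
    stop("both reciprocal crosses (NN99, 99NN) must be present")
  out <- list()
  for (cr in c("NN99", "99NN")) {
    d <- dm$d[dm$samples$cross == cr, , drop = FALSE]
    if (nrow(d) < 20) stop("need >= 20 individuals per cross (", cr, ")")
    mat <- if (cr == "NN99") d else 4L - d
    base <- tabulate(dm$d[dm$samples$cross == cr, ] + 1L, nbins = 5)
    basep <- base / sum(base)
    if (any(basep == 0))
      warning("state(s) absent genome-wide in ", cr,
              "; chi-square run on the observed categories")
    keep <- basep > 0
    np <- colSums(!is.na(mat))
    frac_m <- colSums(mat >= 1L, na.rm = TRUE) / np
    frac_p <- colSums(mat <= 3L, na.rm = TRUE) / np   # >=1 paternal copy
    # per-bin five-state counts vs baseline: vectorised Pearson GOF
    cnt <- vapply(0:4, function(s) colSums(d == s, na.rm = TRUE),
                  numeric(ncol(d)))                    # bins x 5
    expd <- outer(np, basep)
    stat <- rowSums(((cnt - expd)^2 / expd)[, keep, drop = FALSE])
    pval <- stats::pchisq(stat, df = sum(keep) - 1L, lower.tail = FALSE)
    out[[cr]] <- data.frame(
      bin = dm$bins$bin, chrom = dm$bins$chrom, start = dm$bins$start,
      end = dm$bins$end, cross = cr,
      frac_maternal = frac_m, frac_paternal = frac_p, chisq_p = pval,
      maternal_candidate = frac_m > threshold & pval < alpha,
      paternal_candidate = frac_p > threshold & pval < alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("retention_scan", "data.frame")
  res
}

#' Merge candidate bins and classify cytonuclear selection segments
#'
#' Candidate bins are compared across the reciprocal crosses and classified:
#' Group I = maternal homoeolog retained in both crosses (symmetric
#' hetero-cytonuclear incompatibility), Group II = paternal retained in both
#' (symmetric hetero-cytonuclear superiority), Group III = paternal retained
#' in exactly one cross (asymmetric superiority).  Maternal-only-one-cross
#' candidates are reported as `unclassified`.  Runs of same-class bins with
#' gaps of at most `max_gap` bins are merged into segments.
#'
#' @param scan a `retention_scan` from [scan_retention()].
#' @param max_gap largest bin gap bridged when merging (default 1, tolerating
#'   isolated uncalled bins).
#' @return data.frame (class `cyto_segments`): `chrom`, `start`, `end`,
#'   `group` (`I`/`II`/`III`/`unclassified`), `direction`, `crosses`,
#'   `n_bins`.
#' @export
merge_and_classify <- function(scan, max_gap = 1) {
  w <- function(cr, col) {
    s <- scan[scan$cross == cr, ]
    s$bin[s[[col]]]
  }
  m1 <- w("NN99", "maternal_candidate"); m2 <- w("99NN", "maternal_candidate")
  p1 <- w("NN99", "paternal_candidate"); p2 <- w("99NN", "paternal_candidate")
  cls <- list(
    I = list(bins = intersect(m1, m2), dir = "maternal_retained", crosses = "both"),
    II = list(bins = intersect(p1, p2), dir = "paternal_retained", crosses = "both"),
    III_NN99 = list(bins = setdiff(p1, p2), dir = "paternal_retained", crosses = "NN99"),
    III_99NN = list(bins = setdiff(p2, p1), dir = "paternal_retained", crosses = "99NN"),
    U_NN99 = list(bins = setdiff(m1, m2), dir = "maternal_retained", crosses = "NN99"),
    U_99NN = list(bins = setdiff(m2, m1), dir = "maternal_retained", crosses = "99NN")
  )
  bins <- scan[scan$cross == "NN99", c("bin", "chrom", "start", "end")]
  segs <- list()
  for (nm in names(cls)) {
    b <- sort(cls[[nm]]$bins)
    if (!length(b)) next
    grp <- if (nm == "I") "I" else if (nm == "II") "II" else
      if (startsWith(nm, "III")) "III" else "unclassified"
    info <- bins[match(b, bins$bin), ]
    brk <- c(TRUE, diff(b) > max_gap + 1 |
               info$chrom[-1] != info$chrom[-length(b)])
    runid <- cumsum(brk)
    for (r in unique(runid)) {
      sel <- runid == r
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = info$chrom[sel][1], start = min(info$start[sel]),
        end = max(info$end[sel]), group = grp, direction = cls[[nm]]$dir,
        crosses = cls[[nm]]$crosses, n_bins = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(structure(data.frame(chrom = character(0), start = numeric(0),
                                end = numeric(0), group = character(0),
                                direction = character(0), crosses = character(0),
                                n_bins = integer(0)),
                     class = c("cyto_segments", "data.frame")))
  res <- do.call(rbind, segs)
  res <- res[order(res$chrom, res$start), ]
  rownames(res) <- NULL
  class(res) <- c("cyto_segments", "data.frame")
  res
}

#' Cytonuclear-gene enrichment in selection segments
#'
#' 2 x 2 Pearson chi-square (no continuity correction) of cytonuclear-flagged
#' genes (flag `CCEC` or `CEC`) inside versus outside the segments, per group
#' and overall.
#'
#' @param segments a `cyto_segments` table.
#' @param ann an [annotation_table()].
#' @return data.frame per group (+ `all`): gene counts, `chisq`, `p`.
#' @export
annotation_enrichment <- function(segments, ann) {
  if (nrow(segments) == 0) stop("no segments to test")
  flagged <- ann$cytonuclear_flag != "none"
  in_seg_any <- function(segs) {
    hit <- rep(FALSE, nrow(ann))
    for (i in seq_len(nrow(segs)))
      hit <- hit | (ann$chrom == segs$chrom[i] & ann$start < segs$end[i] &
                      ann$end > segs$start[i])
    hit
  }
  one <- function(label, segs) {
    inside <- in_seg_any(segs)
    tab <- matrix(c(sum(flagged & inside), sum(!flagged & inside),
                    sum(flagged & !inside), sum(!flagged & !inside)),
                  2, 2, byrow = TRUE)
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(group = label, n_genes_in = sum(inside),
               n_flagged_in = sum(flagged & inside),
               n_flagged_out = sum(flagged & !inside),
               chisq = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  }
  groups <- intersect(c("I", "II", "III"), unique(segments$group))
  out <- lapply(groups, function(g) one(g, segments[segments$group == g, ]))
  out[[length(out) + 1L]] <- one("all", segments)
  do.call(rbind, out)
}

#' Fitness contrast between retention-conforming and violating individuals
#'
#' For each segment, splits individuals of the affected cross(es) into those
#' conforming to the retained direction (>= 1 copy of the favoured homoeolog
#' everywhere in the segment) and violators, and compares fitness traits with
#' Welch's t-test.
#'
#' @param segments a `cyto_segments` table.
#' @param dm the [dosage_matrix()] used for the scan.
#' @param tt a trait table.
#' @param fitness_traits trait column names to contrast.
#' @return data.frame per segment x trait: group sizes, means, `p` (NA when a
#'   class has fewer than 2 members).
#' @export
fitness_contrast <- function(segments, dm, tt, fitness_traits) {
  out <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    crs <- if (seg$crosses == "both") c("NN99", "99NN") else seg$crosses
    lo <- bin_index(dm$grid, seg$chrom, seg$start)
    hi <- bin_index(dm$grid, seg$chrom, seg$end - 1)
    conf <- logical(0); ids <- character(0)
    for (cr in crs) {
      rows <- which(dm$samples$cross == cr)
      d <- dm$d[rows, lo:hi, drop = FALSE]
      fav <- if ((seg$direction == "maternal_retained") == (cr == "NN99")) d else 4L - d
      conf <- c(conf, apply(fav >= 1L, 1, all))
      ids <- c(ids, rownames(dm$d)[rows])
    }
    for (tr in fitness_traits) {
      y <- tt[[tr]][match(ids, tt$individual)]
      yc <- y[conf & !is.na(y)]; yv <- y[!conf & !is.na(y)]
      p <- if (length(yc) >= 2 && length(yv) >= 2)
        stats::t.test(yv, yc, var.equal = FALSE)$p.value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = seg$chrom, start = seg$start, end = seg$end,
        group = seg$group, trait = tr,
        n_conforming = length(yc), n_violating = length(yv),
        mean_conforming = if (length(yc)) mean(yc) else NA_real_,
        mean_violating = if (length(yv)) mean(yv) else NA_real_,
        p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
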