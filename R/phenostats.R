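#' Variation metrics per group and trait
#'
#' Sample standard deviation (n - 1 denominator), range R = max - min, and
#' coefficient of variation CV = SD / mean for every group x trait cell of a
#' trait table.
#'
#' @param tt a trait table: data.frame with `individual`, `group` and numeric
#'   trait columns.
#' @param traits trait column names (default: all numeric columns).
#' @return data.frame with columns `trait`, `group`, `n`, `mean`, `sd`,
#'   `range`, `cv` (CV is NA when the group mean is zero).
#' @export
variation_metrics <- function(tt, traits = NULL) {
  if (is.null(traits)) traits <- .trait_cols(tt)
  out <- list()
  for (tr in traits) {
    for (grp in unique(tt$group)) {
      x <- tt[[tr]][tt$group == grp]
      x <- x[!is.na(x)]
      if (length(x) < 2) stop("need >= 2 values per group x trait (", tr,
                              " x ", grp, ")")
      m <- mean(x); s <- stats::sd(x)
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, group = grp, n = length(x), mean = m, sd = s,
        range = max(x) - min(x), cv = if (m == 0) NA_real_ else s / m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.trait_cols <- function(tt) {
  setdiff(names(tt)[vapply(tt, is.numeric, TRUE)], c("individual", "group"))
}

#' Transgressive segregation counts
#'
#' Counts tetraploid individuals beyond the extremes of both parental
#' groups: over-transgressive above the larger parental maximum,
#' under-transgressive below the smaller parental minimum; a two-sided exact
#' binomial sign test compares the two counts against a 50:50 split.
#'
#' @param tt a trait table (see [variation_metrics()]).
#' @param parent_groups the two parental group labels.
#' @param tet_groups tetraploid group labels.
#' @param traits trait column names (default: all numeric).
#' @return data.frame per trait: `n_over`, `n_under`, `sign_p`.
#' @export
transgression_counts <- function(tt, parent_groups = c("parent_NPB", "parent_911"),
                                 tet_groups = c("tet_NN99", "tet_99NN"),
                                 traits = NULL) {
  if (is.null(traits)) traits <- .trait_cols(tt)
  if (!all(parent_groups %in% tt$group)) stop("parent group(s) missing")
  tet <- tt$group %in% tet_groups
  if (!any(tet)) stop("no tetraploid individuals")
  out <- lapply(traits, function(tr) {
    pv <- tt[[tr]][tt$group %in% parent_groups]
    tv <- tt[[tr]][tet]
    n_over <- sum(tv > max(pv, na.rm = TRUE), na.rm = TRUE)
    n_under <- sum(tv < min(pv, na.rm = TRUE), na.rm = TRUE)
    p <- if (n_over + n_under == 0) NA_real_ else
      stats::binom.test(n_over, n_over + n_under, 0.5)$p.value
    data.frame(trait = tr, n_over = n_over, n_under = n_under, sign_p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Welch two-sample comparison of a trait between groups
#'
#' @param tt a trait table.
#' @param trait trait column name.
#' @param group_a,group_b group labels to compare.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`.  When both groups
#'   are constant, returns `t = 0, p = 1` if the means are equal and
#'   `t = Inf (signed), p = 0` otherwise.
#' @export
group_compare <- function(tt, trait, group_a, group_b) {
  a <- tt[[trait]][tt$group == group_a]; a <- a[!is.na(a)]
  b <- tt[[trait]][tt$group == group_b]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p = 1, mean_a = mean(a), mean_b = mean(b)))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_a = mean(a), mean_b = mean(b))
}
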