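#' Genetic architecture of a quantitative trait
#'
#' Effects are parameterised on the F-infinity scale used throughout the
#' package: for NPB dosage d in {0..4}, the additive code is
#' `w = (d - 2) / 2` (homozygote contrast +/- 1) and the dominance code is
#' `v = 1` if d is heterozygous (1, 2 or 3), else 0.  A trait value is
#' `y = mu + sum(a * w + k * v) + sum(aa * w_i w_j + ad * w_i v_j +
#' da * v_i w_j + dd * v_i v_j) + Normal(0, sigma^2)`.
#'
#' @param qtl data.frame with columns `bin` (global bin index), `a`
#'   (additive effect) and `k` (dominance effect); may be empty.
#' @param pairs data.frame with columns `bin_i`, `bin_j`, `aa`, `ad`, `da`,
#'   `dd`; may be NULL/empty.
#' @param mu intercept.
#' @param sigma residual standard deviation.
#' @return object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(qtl, pairs = NULL, mu = 0, sigma = 1) {
  if (is.null(pairs))
    pairs <- data.frame(bin_i = integer(0), bin_j = integer(0),
                        aa = numeric(0), ad = numeric(0), da = numeric(0),
                        dd = numeric(0))
  stopifnot(all(is.finite(qtl$a)), all(is.finite(qtl$k)), sigma >= 0,
            is.finite(mu))
  structure(list(qtl = qtl, pairs = pairs, mu = mu, sigma = sigma),
            class = "genetic_architecture")
}

#' F-infinity genotype codes from dosage
#'
#' @param d NPB dosage values in 0..4 (NA propagates).
#' @return list with `w` (additive code, (d-2)/2) and `v` (any-heterozygote
#'   indicator).
#' @export
f_codes <- function(d) {
  list(w = (d - 2) / 2, v = as.numeric(d %in% 1:3) * ifelse(is.na(d), NA, 1))
}

.genetic_value <- function(d_matrix, arch) {
  y <- rep(arch$mu, nrow(d_matrix))
  for (q in seq_len(nrow(arch$qtl))) {
    cd <- f_codes(d_matrix[, arch$qtl$bin[q]])
    y <- y + arch$qtl$a[q] * cd$w + arch$qtl$k[q] * cd$v
  }
  for (p in seq_len(nrow(arch$pairs))) {
    ci <- f_codes(d_matrix[, arch$pairs$bin_i[p]])
    cj <- f_codes(d_matrix[, arch$pairs$bin_j[p]])
    y <- y + arch$pairs$aa[p] * ci$w * cj$w + arch$pairs$ad[p] * ci$w * cj$v +
      arch$pairs$da[p] * ci$v * cj$w + arch$pairs$dd[p] * ci$v * cj$v
  }
  y
}

#' Sample trait values for a simulated population
#'
#' Applies one or more [genetic_architecture()]s to the true dosage of a
#' simulated population and adds Gaussian noise.  Optionally appends
#' reference groups: diploid parents (uniform dosage 4 or 0, i.e. pure NPB /
#' pure 93-11 codes) and F1 hybrids (uniform balanced dosage 2), each with
#' the same residual noise.
#'
#' @param truth a `truth_set` from [simulate_population()].
#' @param architectures a named list of [genetic_architecture()]s, one per
#'   trait (a single architecture is accepted and named `trait1`).
#' @param n_parents,n_f1 individuals per parent / F1 group (0 to omit).
#' @param seed optional RNG seed.
#' @return a `trait_table` data.frame: `individual`, `group` (one of
#'   `parent_NPB`, `parent_911`, `F1_N9`, `F1_9N`, `tet_NN99`, `tet_99NN`)
#'   and one numeric column per trait.
#' @export
sample_phenotypes <- function(truth, architectures, n_parents = 12,
                              n_f1 = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(architectures, "genetic_architecture"))
    architectures <- list(trait1 = architectures)
  ids <- rownames(truth$dosage$d)
  group <- paste0("tet_", truth$dosage$samples$cross)
  d <- truth$dosage$d
  B <- ncol(d)
  ref <- list(parent_NPB = 4L, parent_911 = 0L, F1_N9 = 2L, F1_9N = 2L)
  refn <- c(parent_NPB = n_parents, parent_911 = n_parents,
            F1_N9 = n_f1, F1_9N = n_f1)
  for (gname in names(ref)) {
    n <- refn[[gname]]
    if (n > 0) {
      block <- matrix(ref[[gname]], n, B)
      rownames(block) <- sprintf("%s_%02d", gname, seq_len(n))
      d <- rbind(d, block)
      group <- c(group, rep(gname, n))
      ids <- c(ids, rownames(block))
    }
  }
  out <- data.frame(individual = ids, group = group, stringsAsFactors = FALSE)
  for (tr in names(architectures)) {
    arch <- architectures[[tr]]
    out[[tr]] <- .genetic_value(d, arch) +
      stats::rnorm(nrow(d), 0, arch$sigma)
  }
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Random default architectures for a battery of traits
#'
#' Each trait draws a few additive QTL, one dominance QTL and one epistatic
#' pair at random bins, with effect sizes standardised so the genetic signal
#' is comparable to the residual noise (broad-sense heritability around 0.5
#' at balanced dosage frequencies).
#'
#' @param grid a [genome_grid()].
#' @param n_traits number of traits (default 21).
#' @param n_additive additive QTL per trait.
#' @param sigma residual sd per trait.
#' @param seed optional RNG seed.
#' @return named list of [genetic_architecture()]s.
#' @export
default_architectures <- function(grid, n_traits = 21, n_additive = 3,
                                  sigma = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  B <- grid$n_bins_total
  lapply(stats::setNames(seq_len(n_traits), sprintf("trait%02d", seq_len(n_traits))),
         function(t) {
    bins <- sample.int(B, n_additive + 3)
    qtl <- data.frame(bin = bins[seq_len(n_additive + 1)],
                      a = c(stats::rnorm(n_additive, 0, 1.2), 0),
                      k = c(rep(0, n_additive), stats::rnorm(1, 0, 1)))
    pairs <- data.frame(bin_i = bins[n_additive + 2], bin_j = bins[n_additive + 3],
                        aa = stats::rnorm(1, 0, 0.8), ad = 0, da = 0,
                        dd = stats::rnorm(1, 0, 0.8))
    genetic_architecture(qtl, pairs, mu = 10, sigma = sigma)
  })
}
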