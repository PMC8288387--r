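#' Genome grid for binned dosage analysis
#'
#' Defines the coordinate system used throughout the package: chromosomes with
#' lengths and centromere midpoints, carved into fixed-width analysis bins
#' (default 5 kb) plus coarser regional bins (default 500 kb) used only to
#' label pericentromeric and subtelomeric territory.  All intervals in the
#' package are 0-based half-open; the last bin of a chromosome may be short.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param centromeres named numeric vector of centromere midpoints in bp
#'   (same names as `chrom_lengths`), each within `[0, length)`.
#' @param bin_width analysis bin width in bp (default 5000).
#' @param region_bin_width regional bin width in bp used for the
#'   pericentromeric/subtelomeric annotation (default 500000).
#' @return an object of class `genome_grid`.
#' @export
genome_grid <- function(chrom_lengths, centromeres,
                        bin_width = 5000, region_bin_width = 5e5) {
  if (is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (!all(names(chrom_lengths) %in% names(centromeres)))
    stop("centromeres must cover every chromosome")
  centromeres <- centromeres[names(chrom_lengths)]
  if (any(centromeres < 0) || any(centromeres >= chrom_lengths))
    stop("centromere must lie within [0, length)")
  if (bin_width <= 0 || bin_width > min(chrom_lengths))
    stop("bin_width must be positive and no larger than the shortest chromosome")
  n_bins <- as.integer(ceiling(chrom_lengths / bin_width))
  offset <- c(0L, cumsum(n_bins))[seq_along(n_bins)]
  names(offset) <- names(chrom_lengths)
  g <- structure(list(
    chromosomes = data.frame(chrom = names(chrom_lengths),
                             length = unname(chrom_lengths),
                             centromere = unname(centromeres),
                             n_bins = n_bins,
                             offset = unname(offset),
                             stringsAsFactors = FALSE),
    bin_width = bin_width,
    region_bin_width = region_bin_width,
    n_bins_total = sum(n_bins)
  ), class = "genome_grid")
  g
}

#' @export
print.genome_grid <- function(x, ...) {
  cat(sprintf("genome_grid: %d chromosomes, %d bins of %d bp (regional bins %g bp)\n",
              nrow(x$chromosomes), x$n_bins_total, x$bin_width, x$region_bin_width))
  invisible(x)
}

#' Bin table of a genome grid
#'
#' @param grid a [genome_grid()].
#' @return data.frame with one row per bin: `chrom`, `start`, `end`
#'   (0-based half-open) and the global bin index `bin`.
#' @export
grid_bins <- function(grid) {
  ch <- grid$chromosomes
  out <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    start <- seq(0, by = grid$bin_width, length.out = ch$n_bins[i])
    data.frame(chrom = ch$chrom[i], start = start,
               end = pmin(start + grid$bin_width, ch$length[i]),
               stringsAsFactors = FALSE)
  }))
  out$bin <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Map genomic positions to global bin indices
#'
#' @param grid a [genome_grid()].
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 0-based positions.
#' @return integer vector of global bin indices (1-based into [grid_bins()]).
#' @export
bin_index <- function(grid, chrom, pos) {
  ch <- grid$chromosomes
  i <- match(chrom, ch$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  if (any(pos < 0) || any(pos >= ch$length[i]))
    stop("position outside chromosome bounds")
  as.integer(ch$offset[i] + floor(pos / grid$bin_width) + 1)
}

#' Regional class of every analysis bin
#'
#' Classifies each analysis bin as pericentromeric (the three consecutive
#' regional bins harbouring the centromere), subtelomeric (the four
#' consecutive regional bins from the end of each chromosomal arm) or other.
#'
#' @param grid a [genome_grid()].
#' @return factor of length `grid$n_bins_total` with levels
#'   `pericentromeric`, `subtelomeric`, `other`.
#' @export
region_classes <- function(grid) {
  ch <- grid$chromosomes
  rbw <- grid$region_bin_width
  cls <- character(grid$n_bins_total)
  bins <- grid_bins(grid)
  for (i in seq_len(nrow(ch))) {
    len <- ch$length[i]
    if (len < 3 * rbw + 8 * rbw)
      stop("chromosome ", ch$chrom[i],
           " too short to host pericentromeric and subtelomeric classes")
    cen_rbin <- floor(ch$centromere[i] / rbw)      # 0-based regional bin
    peri <- c((cen_rbin - 1) * rbw, (cen_rbin + 2) * rbw)
    peri[1] <- max(peri[1], 0)
    sub_lo <- c(0, 4 * rbw)
    n_rbin <- ceiling(len / rbw)
    sub_hi <- c((n_rbin - 4) * rbw, len)
    idx <- which(bins$chrom == ch$chrom[i])
    mid <- (bins$start[idx] + bins$end[idx]) / 2
    k <- rep("other", length(idx))
    k[mid >= sub_lo[1] & mid < sub_lo[2]] <- "subtelomeric"
    k[mid >= sub_hi[1] & mid < sub_hi[2]] <- "subtelomeric"
    k[mid >= peri[1] & mid < peri[2]] <- "pericentromeric"
    cls[idx] <- k
  }
  factor(cls, levels = c("pericentromeric", "subtelomeric", "other"))
}

#' Rice-like default grid
#'
#' Convenience constructor: `n_chrom` chromosomes of equal length with the
#' centromere at 40% of the chromosome.
#'
#' @param n_chrom number of chromosomes (default 12, the rice karyotype).
#' @param chrom_length chromosome length in bp.
#' @param bin_width,region_bin_width see [genome_grid()].
#' @return a `genome_grid`.
#' @export
default_grid <- function(n_chrom = 12, chrom_length = 3e7,
                         bin_width = 5000, region_bin_width = 5e5) {
  nm <- sprintf("chr%02d", seq_len(n_chrom))
  genome_grid(stats::setNames(rep(chrom_length, n_chrom), nm),
              stats::setNames(rep(0.4 * chrom_length, n_chrom), nm),
              bin_width = bin_width, region_bin_width = region_bin_width)
}
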