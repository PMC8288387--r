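#' Pedigree specification for a reciprocal selfing design
#'
#' The study design this emulates: one colchicine-doubled S0 tetraploid per
#' cross direction (NN99 = NPB maternal, 99NN = 93-11 maternal), selfed for
#' `generations` successive generations; lines are propagated by single-seed
#' descent and expanded to `individuals_per_line` sibs in the final
#' generation.
#'
#' @param generations number of selfing generations g (default 4, i.e. S4).
#' @param lines_per_cross number of selfed lines founded per cross direction.
#' @param individuals_per_line sibs genotyped per line at generation g.
#' @param crosses cross directions to simulate.
#' @return object of class `pedigree_spec`.
#' @export
pedigree_spec <- function(generations = 4, lines_per_cross = 18,
                          individuals_per_line = 6,
                          crosses = c("NN99", "99NN")) {
  stopifnot(generations >= 1, lines_per_cross >= 1, individuals_per_line >= 1,
            all(crosses %in% c("NN99", "99NN")))
  structure(list(generations = generations, lines_per_cross = lines_per_cross,
                 individuals_per_line = individuals_per_line, crosses = crosses),
            class = "pedigree_spec")
}

#' Homoeologous-exchange model
#'
#' Exchanges arise as reciprocal crossovers between one chromatid of each
#' subgenome.  The count transmitted per meiosis per chromosome quartet is
#' Poisson with mean `2 * lambda` (two homoeologous pairs per quartet;
#' `lambda` is the per-chromosome-pair per-meiosis rate, n = 24 pairs for the
#' 12-chromosome rice karyotype).  Breakpoint positions follow a positional
#' weight profile: depleted around the centromere, elevated at subtelomeres.
#'
#' @param lambda HE rate per chromosome pair per meiosis (default 0.75, so
#'   24 * 0.75 = 18 exchanges per meiosis genome-wide).
#' @param peri_weight,subtelo_weight,base_weight relative placement weights
#'   for pericentromeric, subtelomeric and other bins (defaults 0.5 / 2 / 1).
#' @param weights optional explicit per-boundary weight vector (overrides the
#'   regional profile); length `n_bins_total`, indexed by the bin to the right
#'   of the boundary.
#' @return object of class `he_model`.
#' @export
he_model <- function(lambda = 0.75, peri_weight = 0.5, subtelo_weight = 2,
                     base_weight = 1, weights = NULL) {
  stopifnot(lambda >= 0, peri_weight >= 0, subtelo_weight >= 0, base_weight >= 0)
  if (!is.null(weights) && any(weights < 0)) stop("weights must be >= 0")
  structure(list(lambda = lambda, peri_weight = peri_weight,
                 subtelo_weight = subtelo_weight, base_weight = base_weight,
                 weights = weights), class = "he_model")
}

.he_weights <- function(he, grid) {
  if (he$lambda == 0) return(rep(1, grid$n_bins_total))
  if (!is.null(he$weights)) {
    if (length(he$weights) != grid$n_bins_total)
      stop("weights must have one entry per bin")
    return(he$weights)
  }
  cls <- region_classes(grid)
  w <- rep(he$base_weight, grid$n_bins_total)
  w[cls == "pericentromeric"] <- he$peri_weight
  w[cls == "subtelomeric"] <- he$subtelo_weight
  w
}

#' Cytonuclear viability-selection specification
#'
#' Offspring that carry zero copies of the required parental homoeolog
#' anywhere in a listed segment are rejected (and redrawn) with probability
#' `s`.  The maternal homoeolog is NPB in cross NN99 and 93-11 in 99NN.
#'
#' @param chrom,start,end segment coordinates (0-based half-open bp).
#' @param mode `"require_maternal"` or `"require_paternal"`.
#' @param cross cross direction(s) affected: `"NN99"`, `"99NN"` or `"both"`.
#' @param s selection coefficient in `[0, 1]` (1 = lethal).
#' @return object of class `selection_spec` (a data.frame).
#' @export
selection_spec <- function(chrom, start, end, mode, cross = "both", s = 1) {
  df <- data.frame(chrom = chrom, start = start, end = end, mode = mode,
                   cross = cross, s = s, stringsAsFactors = FALSE)
  if (!all(df$mode %in% c("require_maternal", "require_paternal")))
    stop("mode must be require_maternal or require_paternal")
  if (!all(df$cross %in% c("NN99", "99NN", "both"))) stop("bad cross value")
  if (any(df$s < 0 | df$s > 1)) stop("s must be in [0, 1]")
  class(df) <- c("selection_spec", "data.frame")
  df
}

#' Simulate a diagnostic SNP panel on a fresh genome grid
#'
#' SNP positions are uniform within each chromosome at the requested density;
#' bins can optionally be topped up to a minimum SNP count (positions uniform
#' within the bin) to guarantee informative coverage everywhere.
#'
#' @param n_chrom,chrom_length,bin_width grid geometry (see [default_grid()]).
#' @param snp_density expected SNPs per bp (e.g. 1/500).
#' @param min_per_bin minimum SNPs per bin after top-up (default 0 = none).
#' @param seed optional RNG seed.
#' @return list with elements `panel` (a [snp_panel()]) and `grid`.
#' @export
make_panel_and_grid <- function(n_chrom = 12, chrom_length = 3e7,
                                snp_density = 1 / 500, bin_width = 5000,
                                min_per_bin = 0, seed = NULL) {
  if (snp_density <= 0) stop("snp_density must be > 0")
  if (bin_width > chrom_length) stop("bin_width exceeds chromosome length")
  if (!is.null(seed)) set.seed(seed)
  grid <- default_grid(n_chrom, chrom_length, bin_width)
  bases <- c("A", "C", "G", "T")
  chroms <- grid$chromosomes$chrom
  pan <- lapply(seq_along(chroms), function(i) {
    n <- stats::rpois(1, chrom_length * snp_density)
    pos <- sort(sample.int(chrom_length, n))
    if (min_per_bin > 0) {
      cnt <- tabulate(floor((pos - 1) / bin_width) + 1L,
                      nbins = grid$chromosomes$n_bins[i])
      short <- which(cnt < min_per_bin)
      if (length(short)) {
        extra <- unlist(lapply(short, function(b) {
          lo <- (b - 1) * bin_width
          hi <- min(b * bin_width, chrom_length)
          lo + sample.int(hi - lo, min_per_bin - cnt[b])
        }))
        pos <- sort(unique(c(pos, extra)))
      }
    }
    pos <- unique(pos)
    data.frame(chrom = chroms[i], pos = pos - 1L, stringsAsFactors = FALSE)
  })
  pan <- do.call(rbind, pan)
  a1 <- sample(bases, nrow(pan), replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), "")
  list(panel = snp_panel(pan$chrom, pan$pos, a1, a2), grid = grid)
}

## One meiosis: parent haplotype matrix (4 x B; rows 1:2 subgenome A, rows
## 3:4 subgenome B; entries 1 = NPB ancestry) -> one gamete (A chromatid, B
## chromatid) plus the HE junctions realized on the transmitted chromatids.
.meiosis <- function(h, grid, lambda, weights) {
  ch <- grid$chromosomes
  B <- grid$n_bins_total
  gamA <- integer(B); gamB <- integer(B)
  ev_chrom <- character(0); ev_bin <- integer(0)
  for (i in seq_len(nrow(ch))) {
    nb <- ch$n_bins[i]
    cols <- ch$offset[i] + seq_len(nb)
    hA <- h[1:2, cols, drop = FALSE]
    hB <- h[3:4, cols, drop = FALSE]
    if (nb >= 2) {
      # obligate homologous crossover per bivalent, uniform interior boundary
      co <- sample.int(nb - 1L, 1)
      sA <- sample.int(2L, 1)
      gA <- c(hA[sA, 1:co], hA[3L - sA, (co + 1L):nb])
      co <- sample.int(nb - 1L, 1)
      sB <- sample.int(2L, 1)
      gB <- c(hB[sB, 1:co], hB[3L - sB, (co + 1L):nb])
    } else {
      gA <- hA[sample.int(2L, 1), ]
      gB <- hB[sample.int(2L, 1), ]
    }
    n_he <- stats::rpois(1, 2 * lambda)
    if (n_he > 0 && nb >= 2) {
      w <- weights[cols][-1]            # boundary j sits left of bin j+1
      pos <- sample.int(nb - 1L, n_he, replace = TRUE, prob = w)
      side_a <- stats::runif(n_he) < 0.5
      for (k in seq_len(n_he)) {
        p <- pos[k]
        tail <- (p + 1L):nb
        if (side_a[k]) {
          gA[tail] <- hB[sample.int(2L, 1), tail]
        } else {
          gB[tail] <- hA[sample.int(2L, 1), tail]
        }
      }
      ev_chrom <- c(ev_chrom, rep(ch$chrom[i], n_he))
      ev_bin <- c(ev_bin, pos)
    }
    gamA[cols] <- gA; gamB[cols] <- gB
  }
  list(A = gamA, B = gamB,
       events = data.frame(chrom = ev_chrom, boundary_bin = ev_bin,
                           stringsAsFactors = FALSE))
}

.self_offspring <- function(parent, grid, lambda, weights, sel, cross,
                            max_tries = 10000L) {
  for (try in seq_len(max_tries)) {
    g1 <- .meiosis(parent$h, grid, lambda, weights)
    g2 <- .meiosis(parent$h, grid, lambda, weights)
    h <- rbind(g1$A, g2$A, g1$B, g2$B)
    ok <- TRUE
    if (!is.null(sel) && nrow(sel) > 0) {
      for (r in seq_len(nrow(sel))) {
        if (!(sel$cross[r] == "both" || sel$cross[r] == cross)) next
        lo <- bin_index(grid, sel$chrom[r], sel$start[r])
        hi <- bin_index(grid, sel$chrom[r], sel$end[r] - 1)
        d <- colSums(h[, lo:hi, drop = FALSE])
        mat <- if (cross == "NN99") d else 4L - d
        copies <- if (sel$mode[r] == "require_maternal") mat else 4L - mat
        if (any(copies == 0L) && stats::runif(1) < sel$s[r]) { ok <- FALSE; break }
      }
    }
    if (ok) {
      ev <- rbind(g1$events, g2$events)
      return(list(h = h, events = rbind(parent$events, ev),
                  n_new = nrow(ev)))
    }
  }
  stop("selection rejection cap reached; segment ", sel$chrom[1], ":",
       sel$start[1], "-", sel$end[1], " may be unsatisfiable")
}

#' Simulate a reciprocal selfing tetraploid population with HE
#'
#' Forward simulation at bin resolution.  The S0 founder of each cross is a
#' fixed heterozygote (dosage 2 everywhere: two NPB homologs in subgenome A,
#' two 93-11 homologs in subgenome B).  Each selfing step unites two gametes
#' from independent meioses of the same parent.  Per meiosis and chromosome
#' quartet: one obligate homologous crossover per bivalent at a uniform
#' position, plus Poisson(`2 * lambda`) homoeologous exchanges at positions
#' drawn from the HE weight profile, each replacing the distal segment of one
#' transmitted chromatid with homoeologous material.  Offspring violating the
#' [selection_spec()] are rejected with probability `s` and redrawn.
#'
#' @param grid a [genome_grid()].
#' @param pedigree a [pedigree_spec()].
#' @param he an [he_model()].
#' @param sel optional [selection_spec()].
#' @param seed optional RNG seed.
#' @param keep_haplotypes keep the 4 x bins ancestry matrices of the final
#'   generation (memory: 4 x bins integers per individual).
#' @return object of class `truth_set`: list with `dosage` (a
#'   [dosage_matrix()] of the final generation), `events` (per-individual
#'   cumulative HE event table over the 2g pedigree meioses, with bp
#'   boundaries), `counts` (named per-individual cumulative HE counts),
#'   `haplotypes` (optional), `grid`, `pedigree`, `he`.
#' @export
simulate_population <- function(grid, pedigree = pedigree_spec(),
                                he = he_model(), sel = NULL, seed = NULL,
                                keep_haplotypes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  weights <- .he_weights(he, grid)
  B <- grid$n_bins_total
  g <- pedigree$generations
  s0 <- list(h = rbind(rep(1L, B), rep(1L, B), rep(0L, B), rep(0L, B)),
             events = data.frame(chrom = character(0), boundary_bin = integer(0),
                                 stringsAsFactors = FALSE))
  finals <- list(); meta <- list()
  for (cross in pedigree$crosses) {
    parents <- rep(list(s0), pedigree$lines_per_cross)
    if (g > 1) {
      for (gen in seq_len(g - 1)) {
        parents <- lapply(parents, .self_offspring, grid = grid,
                          lambda = he$lambda, weights = weights, sel = sel,
                          cross = cross)
      }
    }
    for (l in seq_along(parents)) {
      for (k in seq_len(pedigree$individuals_per_line)) {
        ind <- .self_offspring(parents[[l]], grid, he$lambda, weights, sel, cross)
        id <- sprintf("%s_L%02d_%02d", cross, l, k)
        finals[[id]] <- ind
        meta[[id]] <- data.frame(individual = id,
                                 line = sprintf("%s_L%02d", cross, l),
                                 generation = sprintf("S%d", g), cross = cross,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  ids <- names(finals)
  d <- matrix(NA_integer_, length(ids), B, dimnames = list(ids, NULL))
  for (i in seq_along(finals)) d[i, ] <- colSums(finals[[i]]$h)
  samples <- do.call(rbind, meta)
  rownames(samples) <- NULL
  bins <- grid_bins(grid)
  boundary_of <- function(chrom, bin) {
    # boundary_bin = j means the edge between local bins j and j+1
    off <- grid$chromosomes$offset[match(chrom, grid$chromosomes$chrom)]
    bins$start[off + bin + 1L]
  }
  events <- do.call(rbind, lapply(ids, function(id) {
    ev <- finals[[id]]$events
    if (nrow(ev) == 0)
      return(data.frame(individual = character(0), chrom = character(0),
                        boundary = numeric(0), stringsAsFactors = FALSE))
    data.frame(individual = id, chrom = ev$chrom,
               boundary = boundary_of(ev$chrom, ev$boundary_bin),
               stringsAsFactors = FALSE)
  }))
  counts <- vapply(finals, function(x) nrow(x$events), 0L)
  structure(list(
    dosage = dosage_matrix(d, grid, samples),
    events = events,
    counts = counts,
    haplotypes = if (keep_haplotypes) lapply(finals, `[[`, "h") else NULL,
    grid = grid, pedigree = pedigree, he = he
  ), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d individuals (S%d), mean cumulative HE count %.1f\n",
              nrow(x$dosage$d), x$pedigree$generations, mean(x$counts)))
  invisible(x)
}

#' Sample sequencing allele depths from a simulated population
#'
#' Per SNP and individual, total depth is Poisson(`coverage`) and the NPB
#' read count is Binomial(total, f_d) with
#' `f_d = (d/4) * (1 - 2e) + e` for the true dosage d of the SNP's bin and
#' sequencing/assignment error rate e.
#'
#' @param truth a `truth_set` from [simulate_population()].
#' @param panel a [snp_panel()] on the same grid.
#' @param coverage mean per-SNP depth (default 10).
#' @param error_rate per-read misassignment probability e, `0 <= e < 0.5`.
#' @param seed optional RNG seed.
#' @return an [allele_depth_matrix()].
#' @export
sample_allele_depths <- function(truth, panel, coverage = 10,
                                 error_rate = 0.01, seed = NULL) {
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  grid <- truth$grid
  sbin <- bin_index(grid, panel$chrom, panel$pos)
  f <- (0:4) / 4 * (1 - 2 * error_rate) + error_rate
  n <- nrow(truth$dosage$d); m <- nrow(panel)
  ids <- rownames(truth$dosage$d)
  npb <- matrix(0L, n, m, dimnames = list(ids, NULL))
  ind <- matrix(0L, n, m, dimnames = list(ids, NULL))
  for (i in seq_len(n)) {
    dsnp <- truth$dosage$d[i, sbin]
    tot <- stats::rpois(m, coverage)
    k <- stats::rbinom(m, tot, f[dsnp + 1L])
    npb[i, ] <- k
    ind[i, ] <- tot - k
  }
  allele_depth_matrix(npb, ind, panel)
}

#' Sample homoeolog expression counts
#'
#' Dosage-coupled genes express the NPB homoeolog in proportion to its DNA
#' dosage (NPB transcript count Binomial(total, d/4), or beta-binomial when
#' `overdispersion > 0`); uncoupled genes are fixed at a 1:1 homoeolog ratio
#' regardless of dosage.
#'
#' @param truth a `truth_set`.
#' @param genes data.frame with columns `gene`, `chrom`, `pos` (0-based
#'   point position used to assign the gene to a bin) and logical `coupled`.
#' @param total_reads per-gene total transcript reads (scalar or per-gene).
#' @param overdispersion beta-binomial overdispersion rho in `[0, 1)`;
#'   0 gives the plain binomial.
#' @param tissues character vector of tissue labels (counts drawn
#'   independently per tissue).
#' @param seed optional RNG seed.
#' @return data.frame (class `expression_counts`) with columns `gene`,
#'   `individual`, `tissue`, `chrom`, `pos`, `reads_npb`, `reads_ind`.
#' @export
sample_expression <- function(truth, genes, total_reads = 400,
                              overdispersion = 0, tissues = "leaf",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(overdispersion >= 0, overdispersion < 1)
  gbin <- bin_index(truth$grid, genes$chrom, genes$pos)
  tot <- rep_len(total_reads, nrow(genes))
  out <- list()
  ids <- rownames(truth$dosage$d)
  for (ts in tissues) {
    for (j in seq_len(nrow(genes))) {
      d <- truth$dosage$d[, gbin[j]]
      if (all(is.na(d))) {
        warning("gene ", genes$gene[j], " maps to an uncalled bin; skipped")
        next
      }
      p <- if (genes$coupled[j]) d / 4 else rep(0.5, length(d))
      if (overdispersion > 0) {
        ab <- (1 - overdispersion) / overdispersion
        p <- stats::rbeta(length(p), pmax(p * ab, 1e-9), pmax((1 - p) * ab, 1e-9))
      }
      k <- stats::rbinom(length(d), tot[j], p)
      out[[length(out) + 1L]] <- data.frame(
        gene = genes$gene[j], individual = ids, tissue = ts,
        chrom = genes$chrom[j], pos = genes$pos[j],
        reads_npb = k, reads_ind = tot[j] - k, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("expression_counts", "data.frame")
  res
}
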