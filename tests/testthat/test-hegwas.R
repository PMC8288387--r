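test_that("the four encodings map the five states to their standard codes", {
  grid <- tiny_grid()
  d <- matrix(rep(0:4, length.out = 16), 1, 16)
  dm <- dm_from_states(d, grid)
  first5 <- function(m) unname(m[1, 1:5])
  expect_equal(first5(encode_dosage(dm, "additive")), c(0, 1, 2, 3, 4))
  expect_equal(first5(encode_dosage(dm, "dom_i")), c(0, 1, 1, 1, 0))
  expect_equal(first5(encode_dosage(dm, "dom_ii")), c(0, 2, 2, 2, 1))
  expect_equal(first5(encode_dosage(dm, "dom_iii")), c(1, 2, 2, 2, 0))
  expect_error(encode_dosage(dm, "dom_iv"))
  # NA propagates
  d[1, 3] <- NA
  expect_true(is.na(encode_dosage(dm_from_states(d, grid), "additive")[1, 3]))
})

test_that("label-swap symmetry: additive encoding of 4 - d reverses the codes", {
  grid <- tiny_grid()
  d <- matrix(sample(0:4, 32, replace = TRUE), 2, 16)
  dm <- dm_from_states(d, grid)
  dm_swap <- dm_from_states(4L - d, grid)
  codes <- function(m) as.vector(unclass(m))
  expect_equal(codes(encode_dosage(dm_swap, "additive")),
               codes(4 - encode_dosage(dm, "additive")))
  # dom_i is invariant under the swap; dom_ii and dom_iii exchange roles
  expect_equal(codes(encode_dosage(dm_swap, "dom_i")),
               codes(encode_dosage(dm, "dom_i")))
  expect_equal(codes(encode_dosage(dm_swap, "dom_ii")),
               codes(encode_dosage(dm, "dom_iii")))
})

test_that("Bonferroni threshold arithmetic, including the genome-wide SNP-scale cutoff", {
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  # M implied by the printed threshold: round(0.05 / 1.3395e-7) = 373274
  expect_equal(bonferroni_threshold(0.05, 373274), 1.3395e-7, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.01, 1), 0.01)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("iteration 1 equals a plain single-marker OLS oracle", {
  grid <- default_grid(1, 2e6, region_bin_width = 1e5)
  tr <- simulate_population(grid, pedigree_spec(3, 40, 1), he_model(1.0),
                            seed = 91)
  dm <- tr$dosage
  set.seed(92)
  y <- rnorm(nrow(dm$d))
  tt <- data.frame(individual = rownames(dm$d), group = "t", y = y)
  eg <- encode_dosage(dm, "additive")
  g <- run_gwas(eg, tt, "y", max_iter = 1)
  for (j in sample(which(!is.na(g$scan$p)), 25)) {
    fit <- summary(lm(y ~ eg[, j]))
    expect_equal(g$scan$p[j], fit$coefficients[2, 4], tolerance = 1e-10)
    expect_equal(g$scan$effect[j], fit$coefficients[2, 1], tolerance = 1e-10)
  }
})

test_that("a noiseless additive QTL is the unique, vanishing-p signal", {
  grid <- default_grid(1, 2e6, region_bin_width = 1e5)
  tr <- simulate_population(grid, pedigree_spec(4, 50, 1), he_model(1.0),
                            seed = 93)
  dm <- tr$dosage
  qb <- 200
  y <- 3 + 0.5 * dm$d[, qb]
  tt <- data.frame(individual = rownames(dm$d), group = "t", y = y)
  g <- run_gwas(encode_dosage(dm, "additive"), tt, "y")
  expect_gte(nrow(g$signals), 1)
  # the top signal is the QTL bin (or a perfectly correlated neighbour)
  top <- g$signals$marker[which.min(g$signals$p)]
  expect_equal(cor(dm$d[, top], dm$d[, qb]), 1, tolerance = 1e-12)
  expect_lt(g$scan$p[qb], 1e-200)
})

test_that("segment delineation follows the r > 0.9 rule", {
  grid <- tiny_grid()
  set.seed(94)
  base <- sample(0:4, 30, replace = TRUE)
  d <- matrix(0L, 30, 16)
  d[, 1:16] <- rep(sample(0:4, 30 * 16, replace = TRUE))
  d[, 3] <- base; d[, 4] <- base; d[, 5] <- base       # identical block
  dm <- dm_from_states(d, grid)
  seg <- delineate_segment(dm, 4, r_min = 0.9)
  expect_equal(seg$first_bin, 3)
  expect_equal(seg$last_bin, 5)
  # delineation stops at the chromosome edge (chrA spans bins 1..8)
  d2 <- matrix(rep(base, 16), 30, 16)
  seg2 <- delineate_segment(dm_from_states(d2, grid), 4, r_min = 0.9)
  expect_equal(c(seg2$first_bin, seg2$last_bin), c(1, 8))
  expect_error(delineate_segment(dm_from_states(matrix(2L, 30, 16), grid), 8),
               "variance")
})

test_that("segment length shrinks as the exchange rate rises", {
  grid <- default_grid(1, 2e6, region_bin_width = 1e5)
  len <- vapply(c(0.4, 2.0), function(lam) {
    tr <- simulate_population(grid, pedigree_spec(4, 60, 1), he_model(lam),
                              seed = 95)
    seg <- delineate_segment(tr$dosage, 200, r_min = 0.9)
    seg$last_bin - seg$first_bin + 1
  }, 0)
  expect_gt(len[1], len[2])
})

test_that("candidate gene annotation respects half-open intervals", {
  ann <- annotation_table(data.frame(
    gene = c("inside", "abut_left", "abut_right", "overlap"),
    chrom = "chr01",
    start = c(12000, 5000, 20000, 19000),
    end = c(15000, 10000, 25000, 21000), stringsAsFactors = FALSE))
  segs <- data.frame(chrom = "chr01", start = 10000, end = 20000)
  hits <- annotate_candidates(segs, ann)
  expect_setequal(hits$gene, c("inside", "overlap"))
  expect_equal(nrow(annotate_candidates(segs, ann[0, ])), 0)
})

test_that("GWAS on simulated traits: null control, additive power and
           dominance-specific detection", {
  grid <- default_grid(2, 5e6, region_bin_width = 2.5e5)
  n_seeds <- 6
  null_hits <- additive_hits <- domi_hits <- addmiss_hits <- 0
  for (s in seq_len(n_seeds)) {
    tr <- simulate_population(grid, pedigree_spec(4, 50, 1), he_model(0.75),
                              seed = 100 + s)
    dm <- tr$dosage
    n <- nrow(dm$d)
    qb <- 700
    set.seed(200 + s)
    # null trait
    tt <- data.frame(individual = rownames(dm$d), group = "t",
                     null = rnorm(n), stringsAsFactors = FALSE)
    w <- (dm$d[, qb] - 2) / 2
    a <- sqrt(0.25 / var(w))          # QTL explains ~20% of variance
    tt$add <- 10 + a * w + rnorm(n)
    v <- as.numeric(dm$d[, qb] %in% 1:3)
    k <- sqrt(0.25 / var(v))          # heterozygote advantage, same share
    tt$dom <- 10 + k * v + rnorm(n)
    eg_a <- encode_dosage(dm, "additive")
    eg_d <- encode_dosage(dm, "dom_i")
    hit <- function(g) {
      if (nrow(g$signals) == 0) return(FALSE)
      any(abs(g$signals$marker - qb) <= 25 |
            vapply(g$signals$marker, function(b)
              isTRUE(suppressWarnings(cor(dm$d[, b], dm$d[, qb])) > 0.9), TRUE))
    }
    null_hits <- null_hits + (nrow(run_gwas(eg_a, tt, "null")$signals) > 0)
    additive_hits <- additive_hits + hit(run_gwas(eg_a, tt, "add"))
    domi_hits <- domi_hits + hit(run_gwas(eg_d, tt, "dom"))
    addmiss_hits <- addmiss_hits + hit(run_gwas(eg_a, tt, "dom"))
  }
  expect_lte(null_hits, 1)                 # family-wise control
  expect_gte(additive_hits, n_seeds - 1)   # ~20%-variance QTL is found
  expect_gt(domi_hits, addmiss_hits)       # dom_i sees what additive misses
  expect_gte(domi_hits, n_seeds - 2)
})
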