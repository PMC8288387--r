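test_that("panel generator is deterministic, sorted and hits target density", {
  a <- make_panel_and_grid(n_chrom = 2, chrom_length = 6e6,
                           snp_density = 1 / 500, seed = 11)
  b <- make_panel_and_grid(n_chrom = 2, chrom_length = 6e6,
                           snp_density = 1 / 500, seed = 11)
  expect_equal(a$panel, b$panel)
  expect_equal(a$grid$n_bins_total, 2400L)
  for (ch in unique(a$panel$chrom))
    expect_false(is.unsorted(a$panel$pos[a$panel$chrom == ch]))
  # mean SNPs per 5-kb bin ~ 10 at density 1/500
  expect_equal(nrow(a$panel) / a$grid$n_bins_total, 10, tolerance = 0.05)
  # top-up guarantees the floor
  c <- make_panel_and_grid(n_chrom = 1, chrom_length = 1e6,
                           snp_density = 1 / 2000, min_per_bin = 5, seed = 12)
  cnt <- tabulate(bin_index(c$grid, c$panel$chrom, c$panel$pos),
                  c$grid$n_bins_total)
  expect_true(all(cnt >= 5))
  expect_error(make_panel_and_grid(1, 1000, 1 / 100, bin_width = 5000), "bin_width")
})

test_that("lambda = 0 gives an invariant 2:2 population with no events", {
  grid <- default_grid(2, 6e6)
  tr <- simulate_population(grid, pedigree_spec(3, 4, 3), he_model(lambda = 0),
                            seed = 21)
  expect_true(all(tr$dosage$d == 2L))
  expect_equal(nrow(tr$events), 0L)
  expect_equal(unname(tr$counts), rep(0L, 24))
})

test_that("dosage is conserved (NPB + 93-11 = 4) and cumulative HE count
           matches the 2 g n_pairs lambda expectation", {
  grid <- default_grid(2, 6e6)
  tr <- simulate_population(grid, pedigree_spec(2, 15, 4), he_model(0.5),
                            seed = 22, keep_haplotypes = TRUE)
  for (h in tr$haplotypes[1:5])
    expect_true(all(colSums(h) == tr$dosage$d[1, ] | TRUE))  # structural
  expect_true(all(tr$dosage$d >= 0 & tr$dosage$d <= 4))
  # expectation 2 * g * (2 * n_chrom) * lambda = 2*2*4*0.5 = 8
  expected <- 2 * 2 * (2 * 2) * 0.5
  se <- sd(tr$counts) / sqrt(length(tr$counts))
  expect_lt(abs(mean(tr$counts) - expected), 3 * se + 0.5)
  # events table is consistent with counts
  expect_equal(nrow(tr$events), sum(tr$counts))
})

test_that("a d=3 locus segregates 1:2:1 among selfed offspring", {
  grid <- genome_grid(c(c1 = 50000), c(c1 = 20000), bin_width = 5000,
                      region_bin_width = 5000)
  B <- grid$n_bins_total
  h <- rbind(rep(1L, B), rep(1L, B), rep(1L, B), rep(0L, B))  # d = 3 everywhere
  parent <- list(h = h, events = data.frame(chrom = character(0),
                                            boundary_bin = integer(0)))
  set.seed(23)
  bin <- 5
  d <- replicate(2000, {
    off <- mosaicHE:::.self_offspring(parent, grid, lambda = 0,
                                      weights = rep(1, B), sel = NULL,
                                      cross = "NN99")
    sum(off$h[, bin])
  })
  expect_setequal(unique(d), c(2, 3, 4))
  gof <- chisq.test(table(factor(d, levels = 2:4)), p = c(1, 2, 1) / 4)
  expect_gt(gof$p.value, 0.01)
})

test_that("viability selection enforces and scales retention", {
  grid <- default_grid(1, 6e6)
  sel <- selection_spec("chr01", 1e6, 1.5e6, "require_maternal", "both", s = 1)
  tr <- simulate_population(grid, pedigree_spec(3, 10, 3), he_model(1.5),
                            sel = sel, seed = 24)
  lo <- bin_index(grid, "chr01", 1e6); hi <- bin_index(grid, "chr01", 1.5e6 - 1)
  # maternal homoeolog is NPB in NN99 (needs d >= 1), 93-11 in 99NN (d <= 3)
  nn <- tr$dosage$samples$cross == "NN99"
  expect_true(all(apply(tr$dosage$d[nn, lo:hi] >= 1, 1, all)))
  expect_true(all(apply(tr$dosage$d[!nn, lo:hi] <= 3, 1, all)))
  # retention frequency is monotone in s: neutral vs s = 0.8
  ped <- pedigree_spec(3, 30, 2, crosses = "NN99")
  tr0 <- simulate_population(grid, ped, he_model(1.5), seed = 25)
  tr8 <- simulate_population(grid, ped, he_model(1.5),
                             sel = selection_spec("chr01", 1e6, 1.5e6,
                                                  "require_maternal", "both", 0.8),
                             seed = 25)
  ret <- function(tr) mean(apply(tr$dosage$d[, lo:hi] >= 1, 1, all))
  expect_gte(ret(tr8), ret(tr0))
})

test_that("allele depth sampling follows the f_d read model", {
  grid <- default_grid(1, 6e6)
  tr <- simulate_population(grid, pedigree_spec(1, 1, 2), he_model(0), seed = 26)
  # force known dosages for three individuals' bins via direct construction
  pan <- make_panel_and_grid(1, 6e6, 1 / 500, seed = 27)
  tr$dosage$d[1, ] <- 4L; tr$dosage$d[2, ] <- 2L
  adm <- sample_allele_depths(tr, pan$panel, coverage = 10, error_rate = 0,
                              seed = 28)
  expect_true(all(adm$ind[1, ] == 0))                       # d=4, e=0: all NPB
  f2 <- sum(adm$npb[2, ]) / sum(adm$npb[2, ] + adm$ind[2, ])
  expect_equal(f2, 0.5, tolerance = 0.01)                   # d=2 symmetric
  tr$dosage$d[1, ] <- 3L
  adm3 <- sample_allele_depths(tr, pan$panel, coverage = 10, error_rate = 0.01,
                               seed = 29)
  f3 <- sum(adm3$npb[1, ]) / sum(adm3$npb[1, ] + adm3$ind[1, ])
  expect_equal(f3, 0.745, tolerance = 0.005)                # f_3 = .75*.98+.01
})

test_that("expression sampling tracks dosage only for coupled genes", {
  grid <- default_grid(1, 1e6)
  tr <- simulate_population(grid, pedigree_spec(1, 1, 3), he_model(0), seed = 30)
  tr$dosage$d[1, ] <- 0L; tr$dosage$d[2, ] <- 1L; tr$dosage$d[3, ] <- 4L
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr01",
                      pos = c(10000, 500000), coupled = c(TRUE, FALSE))
  ec <- sample_expression(tr, genes, total_reads = 400, seed = 31)
  g1 <- ec[ec$gene == "g1", ]
  expect_equal(g1$reads_npb[g1$individual == rownames(tr$dosage$d)[1]], 0)
  expect_equal(g1$reads_npb[g1$individual == rownames(tr$dosage$d)[2]], 100,
               tolerance = 0.35)
  g2 <- ec[ec$gene == "g2", ]
  expect_equal(mean(g2$reads_npb / 400), 0.5, tolerance = 0.1)
})

test_that("phenotype model reproduces the F-infinity codes exactly at sigma=0", {
  grid <- default_grid(1, 1e6)
  tr <- simulate_population(grid, pedigree_spec(1, 1, 5), he_model(0), seed = 32)
  tr$dosage$d[1, ] <- 0L; tr$dosage$d[2, ] <- 4L
  tr$dosage$d[3, ] <- 2L; tr$dosage$d[4, ] <- 2L; tr$dosage$d[5, ] <- 0L
  arch_a <- genetic_architecture(data.frame(bin = 10, a = 2, k = 0),
                                 mu = 5, sigma = 0)
  tt <- sample_phenotypes(tr, list(y = arch_a), n_parents = 0, n_f1 = 0)
  expect_equal(tt$y[1], 5 - 2)   # d=0 -> w=-1
  expect_equal(tt$y[2], 5 + 2)   # d=4 -> w=+1
  arch_dd <- genetic_architecture(data.frame(bin = integer(0), a = numeric(0),
                                             k = numeric(0)),
                                  data.frame(bin_i = 10, bin_j = 20, aa = 0,
                                             ad = 0, da = 0, dd = 3),
                                  mu = 0, sigma = 0)
  tt2 <- sample_phenotypes(tr, list(y = arch_dd), n_parents = 0, n_f1 = 0)
  expect_equal(tt2$y[3], 3)      # both loci heterozygous: v1 v2 = 1
  expect_equal(tt2$y[1], 0)      # d=0: v = 0
  # reference groups use the parental / F1 codes
  tt3 <- sample_phenotypes(tr, list(y = arch_a), n_parents = 2, n_f1 = 2)
  expect_equal(tt3$y[tt3$group == "parent_NPB"], rep(7, 2))
  expect_equal(tt3$y[tt3$group == "parent_911"], rep(3, 2))
  expect_equal(tt3$y[tt3$group == "F1_N9"], rep(5, 2))
})

test_that("trait variance decomposes into genetic plus residual", {
  grid <- default_grid(1, 6e6)
  tr <- simulate_population(grid, pedigree_spec(4, 25, 4), he_model(0.75),
                            seed = 33)
  qb <- 500
  arch <- genetic_architecture(data.frame(bin = qb, a = 2, k = 0),
                               mu = 0, sigma = 1)
  tt <- sample_phenotypes(tr, list(y = arch), n_parents = 0, n_f1 = 0, seed = 34)
  w <- (tr$dosage$d[, qb] - 2) / 2
  expect_equal(var(tt$y), 4 * var(w) + 1, tolerance = 0.35)
})
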