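test_that("bin likelihoods pool reads and pick the right argmax state", {
  # one chromosome, 2 bins, single individual; 40 reads in bin 1 all NPB,
  # bin 2 gets 30/40 NPB
  grid <- genome_grid(c(c1 = 10000), c(c1 = 5000), bin_width = 5000,
                      region_bin_width = 2500)
  panel <- snp_panel(rep("c1", 4), c(100L, 200L, 6000L, 7000L),
                     rep("A", 4), rep("G", 4))
  npb <- matrix(c(20L, 20L, 15L, 15L), 1, dimnames = list("i1", NULL))
  ind <- matrix(c(0L, 0L, 5L, 5L), 1, dimnames = list("i1", NULL))
  adm <- allele_depth_matrix(npb, ind, panel)
  bl <- bin_likelihoods(adm, grid, error_rate = 0)
  expect_equal(unname(bl$K[1, ]), c(40L, 30L))
  expect_equal(unname(bl$N[1, ]), c(40L, 40L))
  expect_equal(unname(ml_dosage(bl)[1, 1]), 4L)   # K = N = 40, e = 0
  bl2 <- bin_likelihoods(adm, grid, error_rate = 0.01)
  expect_equal(unname(ml_dosage(bl2)[1, 2]), 3L)  # f_3 = 0.745 maximizes
  # N = 0 -> missing
  adm0 <- allele_depth_matrix(matrix(0L, 1, 4, dimnames = list("i1", NULL)),
                              matrix(0L, 1, 4, dimnames = list("i1", NULL)),
                              panel)
  expect_true(all(is.na(ml_dosage(bin_likelihoods(adm0, grid, 0.01)))))
  # e = 0 with 0 < K < N must stay finite, never NaN
  expect_true(all(is.finite(unlist(mosaicHE:::.emission_ll(bl, 1:2)))))
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  set.seed(41)
  for (rep in 1:60) {
    nb <- sample(2:8, 1)
    ll <- matrix(rnorm(nb * 5, sd = 3), nb, 5)
    tau <- sample(c(1e-4, 1e-2, 0.2), 1)
    vit <- viterbi_on_ll(ll, tau)
    bf <- brute_force_path(ll, tau)
    expect_equal(path_score(vit, ll, tau), bf$score, tolerance = 1e-9)
    expect_equal(vit, bf$path)
  }
})

test_that("Viterbi smooths isolated weak states and finds block boundaries", {
  # weak d=3 bin inside a strong d=2 run is smoothed away at tau = 1e-4
  strong2 <- c(-10, -5, 0, -5, -10)
  weak3 <- c(-6, -3, -1, -0.5, -6)
  ll <- rbind(matrix(strong2, 4, 5, byrow = TRUE), weak3,
              matrix(strong2, 3, 5, byrow = TRUE))
  expect_equal(viterbi_on_ll(ll, 1e-4), rep(2L, 8))
  # two strong blocks -> single switch at the true boundary
  strong3 <- strong2[c(5, 1, 2, 3, 4)]  # favors state index 4 (d=3)
  ll2 <- rbind(matrix(strong2, 4, 5, byrow = TRUE),
               matrix(strong3, 4, 5, byrow = TRUE))
  expect_equal(viterbi_on_ll(ll2, 1e-4), c(rep(2L, 4), rep(3L, 4)))
})

test_that("smoothed dosage matches truth on simulated data and the F1-like
           no-exchange control yields zero events", {
  pg <- make_panel_and_grid(n_chrom = 2, chrom_length = 6e6,
                            snp_density = 1 / 500, min_per_bin = 2, seed = 42)
  tr <- simulate_population(pg$grid, pedigree_spec(3, 4, 3), he_model(0.75),
                            seed = 43)
  adm <- sample_allele_depths(tr, pg$panel, 10, 0.01, seed = 44)
  dm <- viterbi_dosage(bin_likelihoods(adm, pg$grid, 0.01), 1e-4)
  expect_gte(mean(dm$d == tr$dosage$d, na.rm = TRUE), 0.99)
  # every true breakpoint flanked by tracts of >= 3 bins lies within +/- 1 bin
  # of a called one; an isolated tract of 1-2 bins needs two switches whose
  # cost (2 log tau) can exceed its pooled read evidence at 10x for the
  # weakest dosage contrast, so such tracts are smoothed out by design
  tru <- call_breakpoints(tr$dosage)
  cal <- call_breakpoints(dm)
  bw <- pg$grid$bin_width
  multi_bin <- rep(TRUE, nrow(tru))
  for (k in seq_len(nrow(tru))) {
    near <- tru$individual == tru$individual[k] & tru$chrom == tru$chrom[k] &
      abs(tru$boundary - tru$boundary[k]) <= 2 * bw & seq_len(nrow(tru)) != k
    if (any(near)) multi_bin[k] <- FALSE
  }
  for (k in which(multi_bin)) {
    hits <- cal$individual == tru$individual[k] & cal$chrom == tru$chrom[k] &
      abs(cal$boundary - tru$boundary[k]) <= bw
    expect_true(any(hits))
  }
  # lambda = 0 control: no recombinant tract may be called
  tr0 <- simulate_population(pg$grid, pedigree_spec(1, 1, 8), he_model(0),
                             seed = 45)
  adm0 <- sample_allele_depths(tr0, pg$panel, 10, 0.01, seed = 46)
  dm0 <- viterbi_dosage(bin_likelihoods(adm0, pg$grid, 0.01), 1e-4)
  expect_equal(nrow(call_breakpoints(dm0)), 0L)
})

test_that("breakpoint calling emits one event per state change and bridges
           missing runs at the gap midpoint", {
  grid <- tiny_grid()
  s <- matrix(2L, 1, 16)
  expect_equal(nrow(call_breakpoints(dm_from_states(s, grid))), 0L)
  s2 <- matrix(c(2L, 2L, 3L, 3L, rep(2L, 12)), 1, 16)
  ev <- call_breakpoints(dm_from_states(s2, grid))
  expect_equal(ev$boundary[1], 10000)
  expect_equal(ev$left_state[1], 2L)
  expect_equal(ev$right_state[1], 3L)
  expect_false(ev$low_resolution[1])
  s3 <- matrix(c(2L, NA, 3L, 3L, 3L, 3L, 3L, 3L, rep(3L, 8)), 1, 16)
  ev3 <- call_breakpoints(dm_from_states(s3, grid))
  expect_equal(nrow(ev3), 1L)
  expect_true(ev3$low_resolution[1])
})

test_that("depth-based euploidy screen flags whole-chromosome depth shifts", {
  pg <- make_panel_and_grid(n_chrom = 2, chrom_length = 6e6,
                            snp_density = 1 / 500, seed = 47)
  tr <- simulate_population(pg$grid, pedigree_spec(1, 1, 3), he_model(0),
                            seed = 48)
  adm <- sample_allele_depths(tr, pg$panel, 10, 0.01, seed = 49)
  scr <- screen_euploidy(adm, pg$grid)
  expect_true(all(scr$verdict == "euploid"))
  # scale one individual's chr2 depths by 0.75 (3-copy mimic of a loss)
  on2 <- pg$panel$chrom == "chr02"
  adm$npb[2, on2] <- as.integer(round(adm$npb[2, on2] * 0.75))
  adm$ind[2, on2] <- as.integer(round(adm$ind[2, on2] * 0.75))
  scr2 <- screen_euploidy(adm, pg$grid)
  expect_equal(scr2$verdict[2], "aneuploid")
  expect_equal(scr2$verdict[1], "euploid")
  expect_true(all(screen_euploidy(adm, pg$grid, tolerance = 1.0)$verdict ==
                    "euploid"))
})

test_that("he_rate divides cumulative counts by 2 g and by chromosome pairs", {
  expect_equal(he_rate(rep(16, 10), generations = 4)$per_meiosis, 2)
  r <- he_rate(rep(190, 5), generations = 5)
  expect_equal(r$per_meiosis, 19.0)
  expect_equal(round(r$per_pair, 2), 0.79)
  expect_equal(he_rate(c(0, 0), generations = 1), list(per_meiosis = 0,
                                                       per_pair = 0))
  # event-table form with a full roster
  ev <- data.frame(individual = c("a", "a", "b"))
  r2 <- he_rate(ev, generations = 1, individuals = c("a", "b", "c"))
  expect_equal(r2$per_meiosis, 0.5)
})
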