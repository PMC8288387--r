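# Shared fixtures, all built in code.

# tiny grid: 2 chromosomes x 40 kb, 5-kb bins (8 bins each)
tiny_grid <- function() {
  genome_grid(c(chrA = 40000, chrB = 40000),
              c(chrA = 20000, chrB = 20000),
              bin_width = 5000, region_bin_width = 5000)
}

# a dosage matrix built directly from a state matrix
dm_from_states <- function(states, grid = tiny_grid(), cross = NULL) {
  rownames(states) <- sprintf("ind%02d", seq_len(nrow(states)))
  samples <- data.frame(individual = rownames(states),
                        stringsAsFactors = FALSE)
  if (!is.null(cross)) samples$cross <- cross
  dosage_matrix(states, grid, samples)
}

# write a small VCF with two parental samples (and optionally AD lines)
write_test_vcf <- function(path, rows, samples = c("NPB", "9311"),
                           format = "GT") {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
              '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}

# brute-force most-likely 5-state path by full enumeration (oracle for the
# Viterbi smoother); ll is an nb x 5 matrix of emission log-likelihoods
brute_force_path <- function(ll, switch_prob) {
  nb <- nrow(ll)
  l_stay <- log(1 - switch_prob); l_sw <- log(switch_prob / 4)
  grid_list <- rep(list(1:5), nb)
  paths <- as.matrix(expand.grid(grid_list))
  score <- ll[1, paths[, 1]]
  if (nb >= 2) for (t in 2:nb) {
    score <- score + ll[t, paths[, t]] +
      ifelse(paths[, t] == paths[, t - 1], l_stay, l_sw)
  }
  best <- which.max(score)
  list(path = unname(paths[best, ]) - 1L, score = max(score))
}

# score of a given path under the same model
path_score <- function(path, ll, switch_prob) {
  nb <- nrow(ll)
  s <- path + 1L
  l_stay <- log(1 - switch_prob); l_sw <- log(switch_prob / 4)
  sc <- ll[1, s[1]]
  if (nb >= 2) for (t in 2:nb)
    sc <- sc + ll[t, s[t]] + ifelse(s[t] == s[t - 1], l_stay, l_sw)
  sc
}

# run the package's Viterbi DP on an explicit nb x 5 emission matrix
viterbi_on_ll <- function(ll, switch_prob) {
  mosaicHE:::.viterbi_ll(ll, switch_prob)
}
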