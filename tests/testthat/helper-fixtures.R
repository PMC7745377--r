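# Fixture builders shared across tests. Everything is generated in code;
# fixed seeds keep results reproducible.

# dense symmetric matrix -> contact_matrix on a single chromosome
cm_from_dense <- function(M, bin_size = 10, chrom = "chrF") {
  n <- nrow(M)
  bins <- make_bins(setNames(n * bin_size, chrom), bin_size)
  ut <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  contact_matrix(tibble::tibble(bin1 = ut[, 1], bin2 = ut[, 2], count = M[ut]), bins)
}

# block "TAD" matrix: two n-bin blocks, within-block value `hi`, cross `lo`
tad_dense <- function(n_block = 20, hi = 5, lo = 1) {
  n <- 2 * n_block
  M <- matrix(lo, n, n)
  M[1:n_block, 1:n_block] <- hi
  M[(n_block + 1):n, (n_block + 1):n] <- hi
  M
}

# standard plaid simulation used by compartment tests
plaid_sim <- function(seed, contrast, n_bins = 200, block = 10, scale = 200) {
  cfg <- sim_config(seed = seed,
                    chrom_lengths = setNames(n_bins * 50e3, "chrS"),
                    bin_size = 50e3, alpha = 1, scale = scale,
                    compartment_block = block, plaid_contrast = contrast)
  simulate_matrix(cfg)
}

prep_matrix <- function(cm, method = "kr") {
  expected_values(balance_matrix(matrix_filters(cm, coverage_fraction = 0.25),
                                 method = method))
}

# TAD simulation with 10 planted boundaries and multiplicative noise
boundary_sim <- function(seed, sigma = 0.2, window_bins = 5) {
  tb <- c(20, 45, 60, 85, 110, 130, 150, 170, 185, 195)
  cfg <- sim_config(seed = seed, chrom_lengths = c(chrT = 10e6), bin_size = 50e3,
                    alpha = 1, scale = 300, tad_boundaries = list(chrT = tb),
                    tad_enrichment = 3, noise_sigma = sigma)
  list(sim = simulate_matrix(cfg), truth_bins = tb)
}

# place n loop anchors with pairwise Chebyshev separation >= min_sep bins,
# so planted loops never sit inside each other's local neighbourhood
place_loops <- function(n = 20, min_sep = 12, max_bin = 190) {
  acc <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(acc) < n && tries < 10000) {
    tries <- tries + 1
    i <- sample(10:150, 1)
    j <- i + sample(12:60, 1)
    if (j > max_bin) next
    if (nrow(acc) && any(pmax(abs(acc[, 1] - i), abs(acc[, 2] - j)) < min_sep)) next
    acc <- rbind(acc, c(i, j))
  }
  tibble::tibble(chrom = "chrL", bin1 = acc[, 1], bin2 = acc[, 2])
}

# loop simulation: 20 planted loops at the given fold on a decay background
loop_sim <- function(seed, fold = 8, scale = 150) {
  set.seed(seed)
  loops <- place_loops(20)
  cfg <- sim_config(seed = seed, chrom_lengths = c(chrL = 10e6), bin_size = 50e3,
                    alpha = 1, scale = scale, loops = loops, loop_fold = fold)
  simulate_matrix(cfg)
}

# brute-force Poisson upper-tail probability, independent of ppois
pois_tail_oracle <- function(obs, lambda) {
  ks <- seq(obs, obs + max(2000, ceiling(10 * lambda)))
  sum(exp(-lambda + ks * log(lambda) - lfactorial(ks)))
}
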