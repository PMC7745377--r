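test_that("correlation matrices have unit diagonal and block structure", {
  sim <- plaid_sim(2, 0.6, n_bins = 100)
  cm <- prep_matrix(sim$matrix)
  corr <- correlation_matrix(cm)
  C <- corr$matrices$chrS
  valid <- which(corr$mask)
  expect_equal(unname(diag(C)[as.character(valid)]), rep(1, length(valid)))
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12, na.rm = TRUE))
  # within-compartment correlations exceed cross-compartment ones
  lab <- sim$truth$compartments$label
  same <- outer(lab, lab, "==")
  off <- abs(outer(seq_along(lab), seq_along(lab), "-")) > 2
  expect_gt(mean(C[same & off], na.rm = TRUE), mean(C[!same & off], na.rm = TRUE))
})

test_that("EV sign recovers planted compartment labels and matches a dense oracle", {
  sim <- plaid_sim(5, 0.6, n_bins = 200)
  cm <- prep_matrix(sim$matrix)
  corr <- correlation_matrix(cm)
  ev <- compartment_ev(corr)
  lab <- sim$truth$compartments$label
  ok <- !is.na(ev$ev)
  acc <- mean(sign(ev$ev[ok]) == ifelse(lab[ok] == "A", 1, -1))
  expect_gte(max(acc, 1 - acc), 0.99)
  # independent oracle: dense eigendecomposition of the same correlation matrix
  C <- corr$matrices$chrS
  valid <- which(corr$mask & !is.na(ev$ev))
  Cs <- C[as.character(valid), as.character(valid)]
  Cs[is.na(Cs)] <- 0
  v <- eigen(Cs, symmetric = TRUE)$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  if (sum(v * ev$ev[valid]) < 0) v <- -v
  expect_equal(unname(v), ev$ev[valid], tolerance = 1e-8)
})

test_that("GC orientation flips the eigenvector sign when needed", {
  sim <- plaid_sim(6, 0.6, n_bins = 60)
  cm <- prep_matrix(sim$matrix)
  corr <- correlation_matrix(cm)
  ev0 <- compartment_ev(corr)
  # synthetic genome: GC-rich where ev0 < 0, so orientation must flip signs
  bs <- cm$bin_size
  seqs <- vapply(seq_len(nrow(cm$bins)), function(k) {
    base <- if (!is.na(ev0$ev[k]) && ev0$ev[k] < 0) "G" else "A"
    strrep(base, bs)
  }, character(1))
  genome <- c(chrS = paste(seqs, collapse = ""))
  ev1 <- compartment_ev(corr, genome = genome)
  ok <- !is.na(ev0$ev)
  expect_equal(ev1$ev[ok], -ev0$ev[ok])
  gc_pos <- mean(ev1$gc[ok][ev1$ev[ok] > 0])
  gc_neg <- mean(ev1$gc[ok][ev1$ev[ok] < 0])
  expect_gte(gc_pos, gc_neg)
})

test_that("degenerate correlation matrices are flagged", {
  cm <- expected_values(cm_from_dense(matrix(1, 10, 10) + diag(10) * 0))
  corr <- correlation_matrix(cm)
  expect_warning(compartment_ev(corr), "Degenerate|degenerate")
})

test_that("saddle grouping: percentiles 5..100 on 100 bins give 20 groups of 5", {
  sim <- plaid_sim(7, 0.5, n_bins = 100)
  cm <- prep_matrix(sim$matrix)
  # ensure exactly 100 usable bins by lifting the mask (all bins valid here)
  skip_if(sum(cm$mask) != 100)
  ev <- compartment_ev(correlation_matrix(cm))
  sad <- saddle_profile(cm, ev, percentiles = seq(5, 100, 5))
  expect_equal(dim(sad$saddle), c(20, 20))
  expect_equal(sad$saddle, t(sad$saddle))
  expect_length(sad$cutoffs, 20)
  expect_true(all(diff(sad$group_ev) >= 0))
})

test_that("saddle of a uniform O/E matrix is flat and its strength 0", {
  n <- 50
  M <- outer(1:n, 1:n, function(i, j) 8 / (1 + abs(i - j)))  # exactly expected
  cm <- expected_values(cm_from_dense(M))
  ev <- tibble::tibble(bin_id = seq_len(n), ev = seq(-1, 1, length.out = n))
  sad <- saddle_profile(cm, ev, percentiles = seq(10, 100, 10))
  expect_equal(unname(sad$saddle[!is.na(sad$saddle)]),
               rep(1, sum(!is.na(sad$saddle))), tolerance = 1e-9)
  expect_equal(compartment_strength(sad), 0, tolerance = 1e-9)
})

test_that("saddle corners exceed the centre on plaid fixtures", {
  sim <- plaid_sim(8, 0.6, n_bins = 200)
  cm <- prep_matrix(sim$matrix)
  ev <- compartment_ev(correlation_matrix(cm))
  sad <- saddle_profile(cm, ev)
  G <- nrow(sad$saddle)
  corners <- mean(c(sad$saddle[1:2, 1:2], sad$saddle[(G - 1):G, (G - 1):G]), na.rm = TRUE)
  centre <- mean(sad$saddle[(G / 2):(G / 2 + 1), (G / 2):(G / 2 + 1)], na.rm = TRUE)
  expect_gt(corners, centre)
})

test_that("compartment strength follows its closed form and rejects log2 input", {
  # AA = BB = 2, AB = 0.5 -> log2(4 / 0.25) = 4
  S <- matrix(0.5, 10, 10)
  S[1:2, 1:2] <- 2; S[9:10, 9:10] <- 2
  sad <- structure(list(saddle = S, group_ev = seq(-1, 1, length.out = 10),
                        cutoffs = seq(-1, 1, length.out = 10),
                        percentiles = seq(10, 100, 10), log2 = FALSE),
                   class = "saddle_result")
  expect_equal(compartment_strength(sad, corner_fraction = 0.2), 4)
  sad$log2 <- TRUE
  expect_error(compartment_strength(sad), "plain O/E")
})

test_that("strength increases monotonically with plaid contrast", {
  strengths <- vapply(c(0.2, 0.45, 0.8), function(ctr) {
    sim <- plaid_sim(11, ctr, n_bins = 150)
    cm <- prep_matrix(sim$matrix)
    ev <- compartment_ev(correlation_matrix(cm))
    compartment_strength(saddle_profile(cm, ev))
  }, numeric(1))
  expect_true(all(diff(strengths) > 0))
})

test_that("shuffled EV labels give near-zero strength", {
  sim <- plaid_sim(13, 0.6, n_bins = 150)
  cm <- prep_matrix(sim$matrix)
  ev <- compartment_ev(correlation_matrix(cm))
  set.seed(99)
  strengths <- replicate(20, {
    shuf <- ev
    ok <- !is.na(shuf$ev)
    shuf$ev[ok] <- sample(shuf$ev[ok])
    compartment_strength(saddle_profile(cm, shuf))
  })
  expect_lt(abs(mean(strengths)), 0.1)
})

test_that("EV is invariant (up to sign) to uniform matrix scaling", {
  sim <- plaid_sim(14, 0.5, n_bins = 80)
  cm <- prep_matrix(sim$matrix)
  ev1 <- compartment_ev(correlation_matrix(cm))
  cm10 <- cm
  cm10$pixels$count <- cm10$pixels$count * 10
  cm10$expected <- NULL
  cm10 <- expected_values(cm10)
  ev2 <- compartment_ev(correlation_matrix(cm10))
  ok <- !is.na(ev1$ev) & !is.na(ev2$ev)
  s <- sign(sum(ev1$ev[ok] * ev2$ev[ok]))
  expect_equal(ev1$ev[ok], s * ev2$ev[ok], tolerance = 1e-6)
})
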