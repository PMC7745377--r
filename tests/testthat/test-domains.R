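test_that("insulation of a constant matrix is zero under both normalisers", {
  cm <- cm_from_dense(matrix(4, 30, 30), bin_size = 10)
  for (nrm in c("arithmetic", "geometric")) {
    ins <- insulation_score(cm, windows = 50, normalisation = nrm)
    sc <- ins$score_50
    expect_true(all(is.na(sc[c(1:5, 26:30)])))  # edge rule: first/last w bins missing
    expect_equal(sc[6:25], rep(0, 20), tolerance = 1e-12)
  }
  expect_error(insulation_score(cm, windows = 10), "at least 2 bins")
})

test_that("a planted two-block TAD fixture has its insulation minimum at the junction", {
  cm <- cm_from_dense(tad_dense(20, hi = 5, lo = 1), bin_size = 10)
  ins <- insulation_score(cm, windows = 50)  # w = 5 bins
  sc <- ins$score_50
  expect_equal(which.min(sc), 20)
  # a single boundary is called, at the junction (symmetric two-bin plateau
  # collapses left of centre)
  b <- call_boundaries(ins, min_score = 0)
  expect_equal(nrow(b), 1)
  expect_equal(b$bin_id, 20)
})

test_that("insulation is invariant to uniform matrix scaling", {
  sim <- boundary_sim(3, sigma = 0.2)
  cm <- prep_matrix(sim$sim$matrix)
  ins1 <- insulation_score(cm, windows = 250e3)
  cm10 <- cm
  cm10$pixels$count <- cm10$pixels$count * 10
  ins2 <- insulation_score(cm10, windows = 250e3)
  ok <- !is.na(ins1$score_250000)
  expect_equal(ins1$score_250000[ok], ins2$score_250000[ok], tolerance = 1e-9)
})

test_that("geometric-mean scores dominate arithmetic-mean scores (AM-GM)", {
  sim <- boundary_sim(5, sigma = 0.2)
  cm <- prep_matrix(sim$sim$matrix)
  a <- insulation_score(cm, windows = 250e3, normalisation = "arithmetic")$score_250000
  g <- insulation_score(cm, windows = 250e3, normalisation = "geometric")$score_250000
  ok <- !is.na(a) & !is.na(g)
  expect_true(all(g[ok] >= a[ok] - 1e-12))
})

test_that("directionality index matches its closed form and symmetries", {
  # A = 1, B = 3 -> E = 2, DI = +((1-2)^2/2 + (3-2)^2/2) = +1
  M <- matrix(0, 3, 3)
  M[2, 1] <- 1; M[1, 2] <- 1
  M[2, 3] <- 3; M[3, 2] <- 3
  cm <- cm_from_dense(M, bin_size = 10)
  di <- directionality_index(cm, windows = 10)
  expect_equal(di$score_10[2], 1)
  # symmetric neighbourhood: DI = 0
  Msym <- matrix(2, 3, 3)
  expect_equal(directionality_index(cm_from_dense(Msym, bin_size = 10),
                                    windows = 10)$score_10[2], 0)
  # mirrored matrix negates the track
  sim <- boundary_sim(7, sigma = 0.1)
  cmx <- prep_matrix(sim$sim$matrix)
  d1 <- directionality_index(cmx, windows = 500e3)$score_500000
  n <- nrow(cmx$bins)
  mir <- cmx
  mir$pixels <- tibble::tibble(bin1 = n + 1 - cmx$pixels$bin2,
                               bin2 = n + 1 - cmx$pixels$bin1,
                               count = cmx$pixels$count)
  mir$bias <- rev(cmx$bias); mir$mask <- rev(cmx$mask)
  d2 <- directionality_index(mir, windows = 500e3)$score_500000
  ok <- !is.na(d1) & !is.na(rev(d2))
  expect_equal(d1[ok], -rev(d2)[ok], tolerance = 1e-9)
  # DI sign is invariant to uniform scaling
  sc10 <- cmx; sc10$pixels$count <- sc10$pixels$count * 10
  d3 <- directionality_index(sc10, windows = 500e3)$score_500000
  ok2 <- !is.na(d1) & d1 != 0
  expect_equal(sign(d1[ok2]), sign(d3[ok2]))
})

test_that("boundary scores combine the two flanking deltas", {
  # minimum 0 flanked by maxima 1.2 and 1.8 -> score 1.5, passes cutoff 1.0
  track <- tibble::tibble(chrom = "chrT", start = 0:6 * 10, end = 1:7 * 10,
                          bin_id = 1:7,
                          score_100 = c(0.5, 1.2, 0.6, 0, 0.9, 1.8, 0.7))
  b <- call_boundaries(track, min_score = 1.0)
  expect_equal(nrow(b), 1)
  expect_equal(b$bin_id, 4)
  expect_equal(b$score, 1.5)
  # min-of-deltas alternative
  b2 <- call_boundaries(track, min_score = 1.0, min_of_deltas = TRUE)
  expect_equal(b2$score, 1.2)
  # monotone track: no minima, no boundaries
  mono <- tibble::tibble(chrom = "chrT", start = 0:5 * 10, end = 1:6 * 10,
                         bin_id = 1:6, score_100 = 1:6 / 2)
  expect_equal(nrow(call_boundaries(mono, min_score = 0)), 0)
  # plateau minimum collapses to the central bin (left of centre when even)
  plat <- tibble::tibble(chrom = "chrT", start = 0:7 * 10, end = 1:8 * 10,
                         bin_id = 1:8,
                         score_100 = c(2, 1, 0, 0, 0, 0, 1, 2))
  bp <- call_boundaries(plat, min_score = 0.5)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$bin_id, 4)
  # entirely missing track warns and returns nothing
  empty <- tibble::tibble(chrom = "chrT", start = 0, end = 10, bin_id = 1,
                          score_100 = NA_real_)
  expect_warning(be <- call_boundaries(empty), "missing")
  expect_equal(nrow(be), 0)
})

test_that("extrema never bridge missing-value gaps", {
  track <- tibble::tibble(chrom = "chrT", start = 0:8 * 10, end = 1:9 * 10,
                          bin_id = 1:9,
                          score_100 = c(2, 0, 2, NA, 2, 0.5, 2, NA, 1))
  b <- call_boundaries(track, min_score = 1.0)
  expect_equal(b$bin_id, c(2, 6))
})

test_that("planted boundaries are recovered at the generating window size", {
  res <- boundary_sim(11, sigma = 0.2)
  cm <- prep_matrix(res$sim$matrix)
  ins <- insulation_score(cm, windows = 250e3)  # 5 bins, the TAD scale here
  b <- call_boundaries(ins, min_score = 0.5)
  hits <- vapply(res$truth_bins, function(tb) {
    any(abs(b$bin_id - tb) <= 1)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
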