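test_that("pairs are binned by fragment midpoint and inputs sum", {
  frags <- structure(
    tibble::tibble(chrom = "chr1", start = seq(0, 90, 10),
                   end = seq(10, 100, 10), frag_id = 1:10),
    chrom_lengths = c(chr1 = 100))
  bins <- make_bins(c(chr1 = 100), 50)
  mk <- function(f1, f2) tibble::tibble(
    chrom1 = "chr1", pos1 = frags$start[f1] + 1, strand1 = "+",
    chrom2 = "chr1", pos2 = frags$start[f2] + 1, strand2 = "-",
    frag1 = f1, frag2 = f2)
  # 3 pairs all joining bin 1 and bin 2 -> single pixel value 3
  cm <- bin_pairs(mk(c(2, 3, 1), c(7, 8, 9)), bins, frags)
  expect_equal(nrow(cm$pixels), 1)
  expect_equal(cm$pixels$count, 3)
  expect_equal(c(cm$pixels$bin1, cm$pixels$bin2), c(1, 2))
  # both fragments in one bin -> diagonal pixel
  cmd <- bin_pairs(mk(1, 3), bins, frags)
  expect_equal(c(cmd$pixels$bin1, cmd$pixels$bin2), c(1, 1))
  # two inputs merge by summation
  cm2 <- bin_pairs(list(mk(c(1, 2), c(7, 8)), mk(c(1, 2, 3, 1, 2), c(6, 7, 8, 9, 6))),
                   bins, frags)
  expect_equal(cm2$pixels$count, 7)
  # unknown chromosome errors
  bad <- mk(1, 2); bad$chrom1 <- "chrZ"
  expect_error(bin_pairs(bad, bins, frags), "absent")
})

test_that("coverage filter masks by absolute or median-relative cutoff", {
  # marginals 10, 2, 9, 11 -> median 9.5, cutoff 2.375 at 25%: bin 2 masked
  cm <- cm_from_dense(diag(c(10, 2, 9, 11)))
  expect_equal(unname(marginals(cm, norm = FALSE)), c(10, 2, 9, 11))
  f <- matrix_filters(cm, coverage_fraction = 0.25)
  expect_equal(f$mask, c(TRUE, FALSE, TRUE, TRUE))
  # all-equal marginals: nothing masked
  cm2 <- cm_from_dense(matrix(1, 3, 3))
  expect_true(all(matrix_filters(cm2, coverage_fraction = 0.25)$mask))
  # zero-marginal bins always masked, even at cutoff 0
  M3 <- matrix(1, 3, 3); M3[2, ] <- 0; M3[, 2] <- 0
  cm3 <- matrix_filters(cm_from_dense(M3), coverage = 0)
  expect_equal(cm3$mask, c(TRUE, FALSE, TRUE))
  expect_error(matrix_filters(cm, coverage = 1, coverage_fraction = 0.1), "not both")
})

test_that("dropping diagonals removes near-diagonal counts", {
  cm <- cm_from_dense(matrix(2, 5, 5))
  f <- matrix_filters(cm, drop_diagonals = 2)
  d <- f$pixels$bin2 - f$pixels$bin1
  expect_true(all(d >= 2))
})

test_that("balancing reproduces the closed-form 2x2 solution", {
  cm <- cm_from_dense(matrix(c(1, 2, 2, 4), 2))
  for (m in c("kr", "ice")) {
    b <- balance_matrix(cm, method = m)
    expect_equal(b$bias, c(1 / sqrt(2), 1 / (2 * sqrt(2))), tolerance = 1e-12)
    norm_vals <- b$pixels$count * b$bias[b$pixels$bin1] * b$bias[b$pixels$bin2]
    expect_equal(norm_vals, rep(0.5, 3), tolerance = 1e-12)
    expect_equal(unname(marginals(b)), c(1, 1), tolerance = 1e-12)
  }
})

test_that("balancing handles symmetric and deficient cases", {
  # all-ones 3x3: every normalised entry 1/3
  b <- balance_matrix(cm_from_dense(matrix(1, 3, 3)), "kr")
  expect_equal(unique(round(b$pixels$count * b$bias[b$pixels$bin1] *
                              b$bias[b$pixels$bin2], 12)), 1 / 3)
  # zero row: bin masked, remaining 2x2 balanced to unit rows
  M <- matrix(1, 3, 3); M[2, ] <- 0; M[, 2] <- 0
  cm <- matrix_filters(cm_from_dense(M))
  b2 <- balance_matrix(cm, "kr")
  expect_equal(b2$bias[2], 0)
  expect_equal(unname(marginals(b2))[c(1, 3)], c(1, 1), tolerance = 1e-9)
  expect_error(balance_matrix(cm_from_dense(matrix(c(0, 1, 1, 0) - 2, 2)), "kr"),
               "Negative")
})

test_that("KR and ICE agree on random positive matrices", {
  set.seed(100)
  for (rep in 1:5) {
    A <- matrix(runif(50 * 50, 0.5, 5), 50)
    A <- (A + t(A)) / 2
    cm <- cm_from_dense(A)
    bk <- balance_matrix(cm, "kr")
    bi <- balance_matrix(cm, "ice")
    expect_lt(max(abs(marginals(bk) - 1)), 1e-6)
    expect_lt(max(abs(marginals(bi) - 1)), 1e-6)
    nk <- bk$pixels$count * bk$bias[bk$pixels$bin1] * bk$bias[bk$pixels$bin2]
    ni <- bi$pixels$count * bi$bias[bi$pixels$bin1] * bi$bias[bi$pixels$bin2]
    expect_lt(max(abs(nk - ni)), 1e-5)
  }
})

test_that("expected values average over valid bin pairs per distance", {
  # 3-bin chromosome, diagonals (5,5,5), (2,4), (1)
  M <- matrix(c(5, 2, 1, 2, 5, 4, 1, 4, 5), 3)
  cm <- expected_values(cm_from_dense(M))
  expect_equal(cm$expected$per_chrom$chrF, c(5, 3, 1))
  # uniform matrix: e(d) = c for all d
  cmu <- expected_values(cm_from_dense(matrix(2.5, 4, 4)))
  expect_equal(cmu$expected$per_chrom$chrF, rep(2.5, 4))
  # masked middle bin: e(1) denominator is 1, not 2
  cmm <- cm_from_dense(M)
  cmm$mask[3] <- FALSE
  cmm <- expected_values(cmm)
  expect_equal(cmm$expected$per_chrom$chrF[2], 2)  # only pair (1,2) counts
})

test_that("expected-value consistency: sums decompose by distance", {
  set.seed(7)
  A <- matrix(rpois(20 * 20, 6), 20); A <- A + t(A)
  cm <- expected_values(cm_from_dense(A), norm = FALSE)
  e <- cm$expected$per_chrom$chrF
  n <- 20
  total_from_e <- sum(e * (n - 0:(n - 1)))
  expect_equal(total_from_e, sum(cm$pixels$count), tolerance = 1e-10)
})

test_that("O/E of an expected-consistent matrix is identically 1", {
  # Toeplitz matrix: value depends only on distance
  n <- 6
  M <- outer(1:n, 1:n, function(i, j) 10 / (1 + abs(i - j)))
  cm <- expected_values(cm_from_dense(M))
  oe <- oe_pixels(cm)
  expect_equal(oe$oe, rep(1, nrow(oe)), tolerance = 1e-12)
  expect_equal(oe_pixels(cm, log2 = TRUE)$oe, rep(0, nrow(oe)), tolerance = 1e-12)
})

test_that("fetch returns symmetric dense matrices and respects the mask", {
  sim <- plaid_sim(2, 0.4, n_bins = 60)
  cm <- prep_matrix(sim$matrix)
  M <- fetch(cm, "chrS")
  expect_equal(M, t(M))
  masked <- which(!cm$mask)
  if (length(masked)) {
    expect_true(all(is.na(M[as.character(masked), ])))
  }
  # O/E of a pixel = value / e(d): check one explicitly
  oe <- fetch(cm, "chrS", oe = TRUE)
  e <- cm$expected$per_chrom$chrS
  valid <- which(cm$mask)
  i <- valid[1]; j <- valid[5]
  expect_equal(oe[as.character(i), as.character(j)],
               M[as.character(i), as.character(j)] / e[j - i + 1])
  expect_error(fetch(cm, "chrZ:0-100"), "not in matrix|parse")
})

test_that("virtual 4C equals the matrix row for a single-bin anchor", {
  sim <- plaid_sim(3, 0.4, n_bins = 40)
  cm <- prep_matrix(sim$matrix)
  bs <- cm$bin_size
  v4c <- virtual_4c(cm, sprintf("chrS:%d-%d", 10 * bs, 11 * bs))
  M <- fetch(cm, "chrS")
  expect_equal(v4c$score, unname(M["11", ]))
  # anchor overlapping a masked bin: masked bin excluded from the mean
  cm2 <- cm
  cm2$mask[11] <- FALSE
  v2 <- virtual_4c(cm2, sprintf("chrS:%d-%d", 10 * bs, 12 * bs))
  M2 <- fetch(cm2, "chrS")
  expect_equal(v2$score[15], unname(M2["12", 15]))  # only bin 12 contributes
})

test_that("matrix containers round-trip exactly", {
  sim <- plaid_sim(4, 0.3, n_bins = 30)
  cm <- prep_matrix(sim$matrix)
  dir <- tempfile()
  write_cfm(cm, dir)
  cm2 <- read_cfm(dir)
  expect_equal(cm2$pixels, cm$pixels)
  expect_equal(cm2$bias, cm$bias)
  expect_equal(cm2$mask, cm$mask)
  expect_equal(cm2$expected$per_chrom$chrS, cm$expected$per_chrom$chrS)
  expect_equal(cm2$chrom_lengths, cm$chrom_lengths)
  # native -> triplet text -> native is value-exact
  f <- tempfile(fileext = ".tsv")
  write_triplets(cm, f)
  bins <- make_bins(cm$chrom_lengths, cm$bin_size)
  cm3 <- read_triplets(f, bins)
  expect_equal(cm3$pixels, cm$pixels)
  # bedgraph2 text round trip
  f2 <- tempfile(fileext = ".tsv")
  write_bedgraph2(cm, f2)
  cm4 <- read_bedgraph2(f2, bins)
  expect_equal(cm4$pixels, cm$pixels)
})

test_that("pixel iteration scales to a million pixels", {
  n <- 1450
  set.seed(1)
  bins <- make_bins(c(big = n * 1000), 1000)
  m <- 1e6
  i <- sample(n, m, replace = TRUE)
  j <- sample(n, m, replace = TRUE)
  px <- tibble::tibble(bin1 = pmin(i, j), bin2 = pmax(i, j), count = 1)
  t0 <- Sys.time()
  cm <- contact_matrix(px, bins)
  marg <- marginals(cm, norm = FALSE)
  expect_equal(sum(marg) + sum(cm$pixels$count[cm$pixels$bin1 == cm$pixels$bin2]),
               2 * m)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 60)
})
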