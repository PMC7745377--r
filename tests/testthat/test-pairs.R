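test_that("reads split at ligation junctions with site restoration", {
  j <- ligation_junction("MboI")
  # X + junction + Y -> X+"GATC" and "GATC"+Y
  out <- split_at_junction("AAACCGATCGATCTTTGG", j, min_length = 4)[[1]]
  expect_equal(out, c("AAACCGATC", "GATCTTTGG"))
  # no junction: read unchanged
  expect_equal(split_at_junction("ACGTACGT", j)[[1]], "ACGTACGT")
  # short left flank dropped by the minimum-length rule
  out2 <- split_at_junction(paste0("GATCGATC", strrep("T", 30)), j, min_length = 20)[[1]]
  expect_length(out2, 1)
  expect_true(endsWith(out2, strrep("T", 30)))
})

test_that("mates are assigned to fragments with orientation and distances", {
  frags <- structure(
    tibble::tibble(chrom = "chr1", start = c(0, 10), end = c(10, 40),
                   frag_id = 1:2),
    chrom_lengths = c(chr1 = 40))
  p <- tibble::tibble(chrom1 = "chr1", pos1 = 5, strand1 = "+",
                      chrom2 = "chr1", pos2 = 30, strand2 = "-")
  a <- assign_pairs(p, frags)
  expect_equal(c(a$frag1, a$frag2), c(1, 2))
  expect_equal(a$orientation, "inward")
  expect_equal(a$rsd1, 5)   # + read faces fragment end at 10
  expect_equal(a$rsd2, 20)  # - read faces fragment start at 10
  expect_equal(a$separation, 0)
  # both mates in one fragment: candidate self-ligation
  p2 <- tibble::tibble(chrom1 = "chr1", pos1 = 12, strand1 = "+",
                       chrom2 = "chr1", pos2 = 30, strand2 = "-")
  a2 <- assign_pairs(p2, frags)
  expect_equal(a2$frag1, a2$frag2)
  # inter-chromosomal: orientation recorded, separation NA
  p3 <- tibble::tibble(chrom1 = "chr9", pos1 = 3, strand1 = "+",
                       chrom2 = "chr1", pos2 = 3, strand2 = "+")
  frags2 <- structure(
    tibble::tibble(chrom = c("chr1", "chr9"), start = c(0, 0), end = c(40, 40),
                   frag_id = 1:2),
    chrom_lengths = c(chr1 = 40, chr9 = 40))
  a3 <- assign_pairs(p3, frags2)
  expect_equal(a3$chrom1, "chr1")  # canonical mate order
  expect_true(is.na(a3$separation))
})

test_that("each filter removes exactly its planted artefact class", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chrP = 10e6), n_pairs = 10000,
                    artefact_fractions = c(duplicate = 0.05, self_ligation = 0.04,
                                           inward_short = 0.03, outward_short = 0.02,
                                           low_mapq = 0.03, unmapped = 0.01,
                                           multimap = 0.01))
  sp <- simulate_pairs(cfg)
  a <- assign_pairs(sp$pairs, sp$fragments)
  res <- filter_pairs(a)
  st <- setNames(res$stats$removed, res$stats$filter)
  tr <- setNames(sp$truth$n, sp$truth$class)
  expect_equal(st[["unmapped"]], unname(tr["unmapped"]))
  expect_equal(st[["multimapping"]], unname(tr["multimap"]))
  expect_equal(st[["mapq"]], unname(tr["low_mapq"]))
  expect_equal(st[["self_ligation"]], unname(tr["self_ligation"]))
  expect_equal(st[["pcr_duplicate"]], unname(tr["duplicate"]))
  expect_equal(st[["ligation_error"]],
               unname(tr["inward_short"] + tr["outward_short"]))
  # conservation: valid + sum(removed) = total, exactly
  expect_equal(st[["valid"]] + sum(st[setdiff(names(st), c("valid", "total"))]),
               st[["total"]])
  expect_equal(st[["total"]], 10000)
})

test_that("filter attribution is stable under input permutation", {
  cfg <- sim_config(seed = 21, chrom_lengths = c(chrP = 5e6), n_pairs = 4000,
                    artefact_fractions = c(duplicate = 0, self_ligation = 0.05,
                                           inward_short = 0.05, outward_short = 0,
                                           low_mapq = 0.05, unmapped = 0,
                                           multimap = 0))
  sp <- simulate_pairs(cfg)
  a <- assign_pairs(sp$pairs, sp$fragments)
  s1 <- filter_pairs(a)$stats
  set.seed(1)
  s2 <- filter_pairs(a[sample(nrow(a)), ])$stats
  expect_equal(s1$removed, s2$removed)
})

test_that("worked filter examples hold", {
  frags <- structure(
    tibble::tibble(chrom = "chr1", start = seq(0, 19000, 1000),
                   end = seq(1000, 20000, 1000), frag_id = 1:20),
    chrom_lengths = c(chr1 = 20000))
  # mapq 2 below threshold 3 -> quality filter
  p <- tibble::tibble(chrom1 = "chr1", pos1 = 100, strand1 = "+", mapq1 = 2L,
                      chrom2 = "chr1", pos2 = 15000, strand2 = "+", mapq2 = 30L)
  r <- filter_pairs(assign_pairs(p, frags))
  expect_equal(r$removed$filtered_by, "mapq")
  # inward pair, restriction-site separation 4000 < 5000 -> ligation error
  p2 <- tibble::tibble(chrom1 = "chr1", pos1 = 500, strand1 = "+", mapq1 = 30L,
                       chrom2 = "chr1", pos2 = 4500, strand2 = "-", mapq2 = 30L)
  a2 <- assign_pairs(p2, frags)
  expect_equal(a2$separation, 3000)  # sites at 1000 and 4000
  r2 <- filter_pairs(a2)
  expect_equal(r2$removed$filtered_by, "ligation_error")
  # two byte-identical pairs: one valid, one PCR duplicate
  p3 <- tibble::tibble(chrom1 = "chr1", pos1 = c(500, 500), strand1 = "-",
                       mapq1 = 30L,
                       chrom2 = "chr1", pos2 = c(15000, 15000), strand2 = "+",
                       mapq2 = 30L)
  r3 <- filter_pairs(assign_pairs(p3, frags))
  expect_equal(nrow(r3$pairs), 1)
  expect_equal(r3$removed$filtered_by, "pcr_duplicate")
})

test_that("self-ligation filter removes all and only same-fragment pairs", {
  cfg <- sim_config(seed = 30, chrom_lengths = c(chrP = 5e6), n_pairs = 3000,
                    artefact_fractions = c(duplicate = 0, self_ligation = 0.1,
                                           inward_short = 0, outward_short = 0,
                                           low_mapq = 0, unmapped = 0, multimap = 0))
  sp <- simulate_pairs(cfg)
  a <- assign_pairs(sp$pairs, sp$fragments)
  res <- filter_pairs(a)
  same_frag <- a$frag1 == a$frag2
  expect_equal(sum(res$removed$filtered_by == "self_ligation"), sum(same_frag))
  expect_false(any(res$pairs$frag1 == res$pairs$frag2))
})

test_that("custom predicate filters can be registered", {
  cfg <- sim_config(seed = 31, chrom_lengths = c(chrP = 5e6), n_pairs = 1000)
  sp <- simulate_pairs(cfg)
  a <- assign_pairs(sp$pairs, sp$fragments)
  conf <- pair_filter_config(custom = function(p) p$pos1 < 1e5)
  res <- filter_pairs(a, conf)
  expect_equal(sum(res$stats$removed[res$stats$filter == "custom"]),
               sum(a$pos1 < 1e5))
})

test_that("orientation fractions converge to 0.25 on random pairs", {
  cfg <- sim_config(seed = 9, chrom_lengths = c(chrP = 10e6), n_pairs = 40000)
  sp <- simulate_pairs(cfg)
  a <- assign_pairs(sp$pairs, sp$fragments)
  d <- pair_diagnostics(a)
  le <- d$ligation_error[d$ligation_error$sep_mid > 8e3 & d$ligation_error$n > 0, ]
  fr <- vapply(split(le, le$orientation),
               function(x) stats::weighted.mean(x$fraction, x$n), numeric(1))
  expect_length(fr, 4)
  # ~3 binomial s.e. at these counts
  expect_true(all(abs(fr - 0.25) < 0.02))
})

test_that("planted inward excess shows up only at short separations", {
  cfg <- sim_config(seed = 12, chrom_lengths = c(chrP = 10e6), n_pairs = 20000,
                    artefact_fractions = c(duplicate = 0, self_ligation = 0,
                                           inward_short = 0.2, outward_short = 0,
                                           low_mapq = 0, unmapped = 0, multimap = 0))
  sp <- simulate_pairs(cfg)
  a <- assign_pairs(sp$pairs, sp$fragments)
  d <- pair_diagnostics(a)
  le <- d$ligation_error[d$ligation_error$orientation == "inward", ]
  low <- le[le$sep_mid < 5e3, ]
  high <- le[le$sep_mid > 8e3 & le$n > 0, ]
  expect_gt(stats::weighted.mean(low$fraction, low$n), 0.5)
  expect_lt(abs(stats::weighted.mean(high$fraction, high$n) - 0.25), 0.03)
})

test_that("empty pair sets give empty diagnostics", {
  d <- pair_diagnostics(tibble::tibble(separation = numeric(), rsd1 = numeric(),
                                       rsd2 = numeric(), orientation = character()))
  expect_equal(nrow(d$ligation_error), 0)
  expect_true(is.na(d$median_insert_size))
})

test_that("pairs text and SAM import agree on the same alignments", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:queryname",
    "@SQ\tSN:chr1\tLN:20000",
    "r1\t67\tchr1\t501\t60\t10M\t=\t15001\t0\tAAAAAAAAAA\t*",
    "r1\t131\tchr1\t15001\t60\t10M\t=\t501\t0\tAAAAAAAAAA\t*"), sam)
  p <- read_pairs_sam(sam)
  expect_equal(nrow(p), 1)
  expect_equal(p$pos1, 500)  # SAM 1-based -> internal 0-based
  expect_equal(p$pos2, 15000)
  expect_equal(p$mapq1, 60)
})
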