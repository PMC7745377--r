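# Deterministic synthetic Hi-C data with known ground truth. One integer
# seed drives everything; matrix and pair generators derive their own
# sub-streams from it, so each is reproducible independently.
#
# The matrix generator draws counts from a Poisson model with mean
#   mu_ij = scale * (1 + |i-j|)^(-alpha) * plaid(i,j) * tad(i,j) * loop(i,j)
# where plaid encodes alternating A/B compartment blocks (same-label pixels
# multiplied by (1 + contrast), cross-label divided by it), tad multiplies
# within-domain pixels, and loop multiplies focal pixels. Multiplicative
# log-normal noise (sigma) perturbs mu before the Poisson draw so counts
# stay integer.

#' Simulation configuration for synthetic Hi-C data
#'
#' @param seed Integer master seed.
#' @param chrom_lengths Named chromosome lengths in bp.
#' @param bin_size Bin size in bp.
#' @param alpha Distance-decay exponent (> 0).
#' @param scale Expected count at distance 0 (sequencing depth proxy).
#' @param compartment_block Compartment block size in bins (0 = no plaid).
#' @param plaid_contrast Plaid contrast c: same-label pixels x(1+c),
#'   cross-label /(1+c).
#' @param tad_boundaries List (per chromosome) of boundary bin indices
#'   (1-based, within chromosome), or `NULL`.
#' @param tad_enrichment Within-TAD multiplicative enrichment (default 2).
#' @param loops Tibble `chrom`, `bin1`, `bin2` (within-chromosome bin
#'   indices) of planted loops, or `NULL`.
#' @param loop_fold Loop fold-enrichment (default 8).
#' @param noise_sigma Log-normal sigma on mu (default 0).
#' @param n_pairs,artefact_fractions Pair-generator settings: total pairs
#'   and named fractions (`duplicate`, `self_ligation`, `inward_short`,
#'   `outward_short`, `low_mapq`, `unmapped`, `multimap`).
#' @param fragment_size Mean synthetic restriction-fragment size in bp.
#' @return Config list for [simulate_matrix()] / [simulate_pairs()].
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrS = 10e6),
                       bin_size = 50e3,
                       alpha = 1.0, scale = 100,
                       compartment_block = 0, plaid_contrast = 0,
                       tad_boundaries = NULL, tad_enrichment = 2,
                       loops = NULL, loop_fold = 8,
                       noise_sigma = 0,
                       n_pairs = 10000,
                       artefact_fractions = c(duplicate = 0, self_ligation = 0,
                                              inward_short = 0, outward_short = 0,
                                              low_mapq = 0, unmapped = 0,
                                              multimap = 0),
                       fragment_size = 500) {
  if (alpha <= 0) stop("Distance-decay exponent alpha must be > 0")
  if (any(artefact_fractions < 0) || sum(artefact_fractions) > 1) {
    stop("Artefact fractions must be in [0,1] and sum to at most 1")
  }
  list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
       bin_size = bin_size, alpha = alpha, scale = scale,
       compartment_block = compartment_block, plaid_contrast = plaid_contrast,
       tad_boundaries = tad_boundaries, tad_enrichment = tad_enrichment,
       loops = loops, loop_fold = loop_fold, noise_sigma = noise_sigma,
       n_pairs = n_pairs, artefact_fractions = artefact_fractions,
       fragment_size = fragment_size)
}

.sub_seed <- function(seed, stream) {
  (as.integer(seed) * 7919L + stream * 104729L) %% 2147483647L
}

#' Simulate a contact matrix with known ground truth
#'
#' @param config From [sim_config()].
#' @return List: `matrix` (raw `contact_matrix`), `truth` with
#'   `boundaries` (BED-style tibble), `loops` (BEDPE-style tibble),
#'   `compartments` (per-bin label tibble), and `mu` (the per-chromosome
#'   expected-intensity matrices).
#' @export
simulate_matrix <- function(config) {
  set.seed(.sub_seed(config$seed, 1L))
  bins <- make_bins(config$chrom_lengths, config$bin_size)
  px <- list(); mus <- list()
  labels <- rep(NA_character_, nrow(bins))
  tb_out <- list(); loop_out <- list()
  for (cc in names(config$chrom_lengths)) {
    rows <- which(bins$chrom == cc)
    n <- length(rows)
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    mu <- config$scale * (1 + D)^(-config$alpha)
    # plaid
    if (config$compartment_block > 0 && config$plaid_contrast > 0) {
      lab <- rep(c("A", "B"), each = config$compartment_block,
                 length.out = n)
      same <- outer(lab, lab, "==")
      mu <- mu * ifelse(same, 1 + config$plaid_contrast, 1 / (1 + config$plaid_contrast))
      labels[rows] <- lab
    }
    # TADs
    tb <- config$tad_boundaries[[cc]]
    if (!is.null(tb)) {
      dom <- findInterval(seq_len(n), c(1, sort(tb)))
      within <- outer(dom, dom, "==")
      mu <- mu * ifelse(within & D > 0, config$tad_enrichment, 1)
      tb_out[[cc]] <- tibble(chrom = cc,
                             start = bins$start[rows[tb]],
                             end = bins$end[rows[tb]],
                             bin_id = bins$bin_id[rows[tb]])
    }
    # loops
    if (!is.null(config$loops)) {
      lp <- config$loops[config$loops$chrom == cc, , drop = FALSE]
      for (r in seq_len(nrow(lp))) {
        i <- lp$bin1[r]; j <- lp$bin2[r]
        mu[i, j] <- mu[i, j] * config$loop_fold
        mu[j, i] <- mu[i, j]
      }
      if (nrow(lp)) {
        loop_out[[cc]] <- tibble(
          chrom1 = cc, start1 = bins$start[rows[lp$bin1]], end1 = bins$end[rows[lp$bin1]],
          chrom2 = cc, start2 = bins$start[rows[lp$bin2]], end2 = bins$end[rows[lp$bin2]],
          bin1 = bins$bin_id[rows[lp$bin1]], bin2 = bins$bin_id[rows[lp$bin2]])
      }
    }
    if (config$noise_sigma > 0) {
      noise <- matrix(exp(rnorm(n * n, 0, config$noise_sigma)), n, n)
      noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
      mu <- mu * noise
    }
    # draw upper triangle
    ut <- which(upper.tri(mu, diag = TRUE), arr.ind = TRUE)
    counts <- rpois(nrow(ut), mu[ut])
    nz <- counts > 0
    px[[cc]] <- tibble(bin1 = bins$bin_id[rows[ut[nz, 1]]],
                       bin2 = bins$bin_id[rows[ut[nz, 2]]],
                       count = counts[nz])
    mus[[cc]] <- mu
  }
  cm <- contact_matrix(bind_rows(px), bins, metadata = list(simulated = TRUE))
  list(matrix = cm,
       truth = list(boundaries = bind_rows(tb_out),
                    loops = bind_rows(loop_out),
                    compartments = mutate(bins, label = labels)),
       mu = mus)
}

#' Simulate read pairs with planted, disjoint artefact classes
#'
#' Generates a synthetic fragment map and a pair table in which valid pairs
#' and each artefact class (PCR duplicates, self-ligations, short
#' inward/outward ligation errors, low mapping quality, unmapped and
#' multimapping mates) are planted in known, disjoint numbers, so filter
#' removal counts can be checked exactly.
#'
#' @param config From [sim_config()].
#' @return List: `pairs` (unassigned pair tibble), `fragments`, and
#'   `truth` (tibble of planted class counts).
#' @export
simulate_pairs <- function(config) {
  set.seed(.sub_seed(config$seed, 2L))
  clen <- config$chrom_lengths
  # regular synthetic fragment map
  frags <- purrr::imap_dfr(as.list(clen), function(len, cc) {
    cuts <- seq(0, len, by = config$fragment_size)
    if (cuts[length(cuts)] < len) cuts <- c(cuts, len)
    tibble(chrom = cc, start = cuts[-length(cuts)], end = cuts[-1])
  })
  frags$frag_id <- seq_len(nrow(frags))
  frags <- .set_chrom_lengths(frags, clen)

  n <- config$n_pairs
  fr <- config$artefact_fractions
  counts <- round(fr * n)
  n_valid <- n - sum(counts)
  le_cut <- 5000

  rand_pos <- function(fid) {
    floor(runif(length(fid), frags$start[fid], frags$end[fid] - 1e-9))
  }
  mk <- function(f1, f2, s1, s2, mapq = 30L, unm = FALSE, mm = FALSE) {
    tibble(chrom1 = frags$chrom[f1], pos1 = rand_pos(f1), strand1 = s1,
           mapq1 = mapq, unmapped1 = unm, multimap1 = FALSE,
           chrom2 = frags$chrom[f2], pos2 = rand_pos(f2), strand2 = s2,
           mapq2 = mapq, unmapped2 = FALSE, multimap2 = mm)
  }
  nf <- nrow(frags)
  sample_far <- function(k) {
    # fragment pairs whose separation comfortably exceeds the ligation-error
    # cutoffs, same chromosome
    gap <- ceiling(le_cut / config$fragment_size) + 2
    f1 <- sample(seq_len(nf - gap - 1), k, replace = TRUE)
    f2 <- f1 + gap + sample(0:min(50, nf - gap - 2), k, replace = TRUE)
    f2 <- pmin(f2, nf)
    cbind(f1, f2)
  }
  rs <- function(k) sample(c("+", "-"), k, replace = TRUE)

  vp <- sample_far(n_valid)
  valid <- mk(vp[, 1], vp[, 2], rs(n_valid), rs(n_valid))

  planted <- list(valid = valid)
  if (counts[["self_ligation"]] > 0) {
    k <- counts[["self_ligation"]]
    f <- sample(seq_len(nf), k, replace = TRUE)
    planted$self_ligation <- mk(f, f, rep("+", k), rep("-", k))
  }
  if (counts[["inward_short"]] > 0) {
    # faced-site separation (gap-1) fragments: positive but below the cutoff
    k <- counts[["inward_short"]]
    f1 <- sample(seq_len(nf - 8), k, replace = TRUE)
    planted$inward_short <- mk(f1, f1 + sample(2:7, k, replace = TRUE),
                               rep("+", k), rep("-", k))
  }
  if (counts[["outward_short"]] > 0) {
    k <- counts[["outward_short"]]
    f1 <- sample(seq_len(nf - 8), k, replace = TRUE)
    planted$outward_short <- mk(f1, f1 + sample(2:7, k, replace = TRUE),
                                rep("-", k), rep("+", k))
  }
  if (counts[["low_mapq"]] > 0) {
    k <- counts[["low_mapq"]]
    p <- sample_far(k)
    planted$low_mapq <- mk(p[, 1], p[, 2], rs(k), rs(k), mapq = 1L)
  }
  if (counts[["unmapped"]] > 0) {
    k <- counts[["unmapped"]]
    p <- sample_far(k)
    planted$unmapped <- mk(p[, 1], p[, 2], rs(k), rs(k), unm = TRUE)
  }
  if (counts[["multimap"]] > 0) {
    k <- counts[["multimap"]]
    p <- sample_far(k)
    planted$multimap <- mk(p[, 1], p[, 2], rs(k), rs(k), mm = TRUE)
  }
  if (counts[["duplicate"]] > 0) {
    k <- counts[["duplicate"]]
    planted$duplicate <- valid[sample(seq_len(nrow(valid)), k, replace = FALSE), ]
  }
  pairs <- bind_rows(planted, .id = "planted_class")
  pairs$planted_class[pairs$planted_class == "duplicate"] <- "duplicate"
  truth <- tibble(class = names(planted),
                  n = unname(vapply(planted, nrow, integer(1))))
  list(pairs = pairs, fragments = frags, truth = truth)
}
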