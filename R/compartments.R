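# A/B compartment analysis: per-chromosome correlation matrix of O/E
# profiles, its first eigenvector (optionally GC-oriented), saddle
# (enrichment) profiles over EV percentiles, and a corner-based
# compartment-strength score.

#' Per-chromosome Pearson correlation matrix of O/E profiles
#'
#' For each chromosome, pixel (i, j) of the correlation matrix is the
#' Pearson correlation between the O/E profile of bin i and bin j
#' (pairwise-complete over valid bins). Bins with more than `max_missing`
#' missing O/E values are masked.
#'
#' @param cm A balanced `contact_matrix`.
#' @param max_missing Mask bins with more than this fraction of missing O/E
#'   values (default 0.9).
#' @return A list of class `correlation_matrix`: per-chromosome dense
#'   matrices (`$matrices`), the bin table (`$bins`) and valid mask
#'   (`$mask`).
#' @export
correlation_matrix <- function(cm, max_missing = 0.9) {
  cm <- .ensure_expected(cm)
  mats <- list()
  mask <- cm$mask
  for (cc in unique(cm$bins$chrom)) {
    rows <- .chrom_bins(cm, cc)
    if (sum(cm$mask[rows]) < 3) {
      warning("Chromosome ", cc, " has fewer than 3 valid bins; skipped")
      next
    }
    O <- .dense_chrom(cm, cc, what = "oe")
    frac_na <- rowMeans(is.na(O))
    drop <- frac_na > max_missing
    mask[rows[drop]] <- FALSE
    O[drop, ] <- NA_real_
    O[, drop] <- NA_real_
    C <- suppressWarnings(cor(O, use = "pairwise.complete.obs"))
    diag(C)[!is.na(diag(C))] <- 1
    dimnames(C) <- list(rows, rows)
    mats[[cc]] <- C
  }
  structure(list(matrices = mats, bins = cm$bins, mask = mask,
                 bin_size = cm$bin_size),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("<correlation_matrix> ", length(x$matrices), " chromosome(s), ",
      sum(x$mask), " valid bins\n", sep = "")
  invisible(x)
}

.gc_fraction <- function(genome, bins) {
  genome <- .as_dnastringset(genome)
  vapply(seq_len(nrow(bins)), function(k) {
    cc <- bins$chrom[k]
    if (!cc %in% names(genome)) return(NA_real_)
    s <- Biostrings::subseq(genome[[cc]], bins$start[k] + 1, bins$end[k])
    f <- Biostrings::alphabetFrequency(s)
    (f[["G"]] + f[["C"]]) / max(1, sum(f[c("A", "C", "G", "T")]))
  }, numeric(1))
}

#' Compartment eigenvector of the correlation matrix
#'
#' The first (largest-eigenvalue) eigenvector of each chromosome's
#' correlation matrix, unit-normalised per chromosome. The sign of the EV is
#' arbitrary from the eigendecomposition; if genome sequence is supplied the
#' sign is fixed per chromosome so that positive-EV bins have the higher
#' mean GC content (the A compartment is typically GC-rich). Without
#' sequence, the sign is fixed so the entry of largest magnitude is
#' positive. Chromosomes can be excluded (e.g. chrY).
#'
#' @param corr A `correlation_matrix`.
#' @param genome Optional genome (FASTA path / named character / DNAStringSet)
#'   for GC orientation.
#' @param exclude Chromosomes to skip (default none).
#' @return Tibble `chrom`, `start`, `end`, `bin_id`, `ev`, `gc` (NA without
#'   genome); masked bins have `ev = NA`.
#' @export
compartment_ev <- function(corr, genome = NULL, exclude = character()) {
  bins <- corr$bins
  ev <- rep(NA_real_, nrow(bins))
  gc <- rep(NA_real_, nrow(bins))
  if (!is.null(genome)) gc <- .gc_fraction(genome, bins)
  for (cc in setdiff(names(corr$matrices), exclude)) {
    C <- corr$matrices[[cc]]
    rows <- as.integer(rownames(C))
    valid <- which(corr$mask[rows] & !is.na(diag(C)))
    if (length(valid) < 3) {
      warning("Degenerate correlation matrix on ", cc,
              " (fewer than 3 correlated bins); eigenvector not computed")
      next
    }
    Cs <- C[valid, valid]
    Cs[is.na(Cs)] <- 0
    eg <- eigen(Cs, symmetric = TRUE)
    if (eg$values[1] - eg$values[length(eg$values)] < 1e-12) {
      warning("Degenerate correlation matrix on ", cc, "; eigenvector unreliable")
    }
    v <- eg$vectors[, 1]
    v <- v / sqrt(sum(v^2))
    gcv <- gc[rows[valid]]
    if (!is.null(genome) && !all(is.na(gcv))) {
      pos_gc <- mean(gcv[v > 0], na.rm = TRUE)
      neg_gc <- mean(gcv[v < 0], na.rm = TRUE)
      if (!is.na(pos_gc) && !is.na(neg_gc) && pos_gc < neg_gc) v <- -v
    } else {
      if (!is.null(genome)) warning("No sequence for ", cc, "; orientation skipped")
      if (v[which.max(abs(v))] < 0) v <- -v
    }
    ev[rows[valid]] <- v
  }
  out <- bins
  out$ev <- ev
  out$gc <- gc
  out
}

#' Saddle (enrichment) profile over compartment-eigenvector percentiles
#'
#' Valid bins are ranked by their EV entry and split into groups at the
#' requested percentiles (rank-based, so percentiles 5, 10, ..., 100 on 100
#' bins give 20 groups of 5). `S[g, h]` is the mean intra-chromosomal O/E
#' over all valid bin pairs with one bin in group g and one in h (implicit
#' zero pixels included).
#'
#' @param cm A balanced `contact_matrix`.
#' @param ev EV tibble from [compartment_ev()].
#' @param percentiles Increasing percentile cutoffs ending at 100
#'   (default `seq(5, 100, 5)`).
#' @param log2 Return mean of O/E then log2 the matrix entries.
#' @return A list of class `saddle_result`: `saddle` (G x G matrix, low-EV
#'   group first), `group_ev` (mean EV per group), `cutoffs` (EV values at
#'   the percentile cuts), `percentiles`.
#' @export
saddle_profile <- function(cm, ev, percentiles = seq(5, 100, 5), log2 = FALSE) {
  stopifnot(all(diff(percentiles) > 0), max(percentiles) == 100)
  cm <- .ensure_expected(cm)
  evv <- ev$ev[match(cm$bins$bin_id, ev$bin_id)]
  usable <- which(cm$mask & !is.na(evv))
  G <- length(percentiles)
  rnk <- rank(evv[usable], ties.method = "first")
  n <- length(usable)
  upper <- ceiling(percentiles / 100 * n)
  grp <- rep(NA_integer_, n_bins(cm))
  grp[usable] <- findInterval(rnk - 1, c(0, upper[-G])) # groups 1..G ascending EV
  grp[usable] <- pmin(grp[usable], G)

  sums <- matrix(0, G, G); cnts <- matrix(0, G, G)
  for (cc in unique(cm$bins$chrom)) {
    rows <- .chrom_bins(cm, cc)
    g <- grp[rows]
    ok <- which(!is.na(g))
    if (length(ok) < 2) next
    O <- .dense_chrom(cm, cc, what = "oe")[ok, ok, drop = FALSE]
    gg <- g[ok]
    for (a in seq_len(G)) {
      ia <- which(gg == a)
      if (!length(ia)) next
      for (b in a:G) {
        ib <- which(gg == b)
        if (!length(ib)) next
        vals <- O[ia, ib, drop = FALSE]
        sums[a, b] <- sums[a, b] + sum(vals, na.rm = TRUE)
        cnts[a, b] <- cnts[a, b] + sum(!is.na(vals))
      }
    }
  }
  S <- ifelse(cnts > 0, sums / cnts, NA_real_)
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  if (log2) S <- base::log2(S)
  group_ev <- vapply(seq_len(G), function(g) mean(evv[grp == g], na.rm = TRUE), numeric(1))
  cutoffs <- quantile(evv[usable], percentiles / 100, names = FALSE)
  structure(list(saddle = S, group_ev = group_ev, cutoffs = cutoffs,
                 percentiles = percentiles, log2 = log2),
            class = "saddle_result")
}

#' @export
print.saddle_result <- function(x, ...) {
  cat("<saddle_result> ", length(x$percentiles), " EV groups",
      if (isTRUE(x$log2)) " (log2 O/E)" else " (O/E)", "\n", sep = "")
  invisible(x)
}

#' Compartment strength from a saddle profile
#'
#' `strength = log2( (AA * BB) / AB^2 )`, where AA is the mean O/E among the
#' top `corner_fraction` of EV groups (A-A contacts), BB among the bottom
#' groups, and AB the cross term. Requires a saddle computed on plain O/E
#' (not log2).
#'
#' @param saddle A `saddle_result` with `log2 = FALSE`.
#' @param corner_fraction Fraction of groups in each corner (default 0.2).
#' @return Scalar strength (0 for a uniform O/E matrix).
#' @export
compartment_strength <- function(saddle, corner_fraction = 0.2) {
  if (isTRUE(saddle$log2)) stop("Compartment strength needs a saddle on plain O/E values")
  G <- nrow(saddle$saddle)
  k <- max(1, ceiling(corner_fraction * G))
  top <- (G - k + 1):G     # highest EV = A
  bot <- 1:k               # lowest EV = B
  AA <- mean(saddle$saddle[top, top], na.rm = TRUE)
  BB <- mean(saddle$saddle[bot, bot], na.rm = TRUE)
  AB <- mean(saddle$saddle[bot, top], na.rm = TRUE)
  if (is.na(AB) || AB == 0) stop("Cross-compartment mean O/E is zero; strength undefined")
  base::log2((AA * BB) / AB^2)
}
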