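# Matrix-level bin filters and balancing. Balancing finds per-bin
# multipliers b_i > 0 so that the normalised matrix m_ij = b_i b_j raw_ij
# has unit row sums over valid bins; KR solves the nonlinear system with the
# Knight-Ruiz inner-outer Newton/conjugate-gradient iteration, ICE with
# Sinkhorn-style alternating marginal division.

#' Mask low-coverage bins and optionally drop near-diagonal counts
#'
#' Bins whose raw marginal falls below a cutoff are masked; the cutoff is
#' either absolute or a fraction of the median non-zero marginal. Bins with
#' zero marginal are always masked. `drop_diagonals = k` removes counts at
#' bin distances `0..k-1`.
#'
#' @param cm A raw `contact_matrix`.
#' @param coverage Absolute marginal cutoff.
#' @param coverage_fraction Fractional cutoff: `fraction * median(non-zero
#'   marginals)`. Only one of the two may be given.
#' @param drop_diagonals Number of leading diagonals to zero (default 0).
#' @return The matrix with updated `mask` (and pixels, when diagonals are
#'   dropped).
#' @export
matrix_filters <- function(cm, coverage = NULL, coverage_fraction = NULL,
                           drop_diagonals = 0) {
  if (!is.null(coverage) && !is.null(coverage_fraction)) {
    stop("Give either an absolute coverage cutoff or a fraction of the median, not both")
  }
  if (drop_diagonals > 0) {
    intra <- cm$bins$chrom[cm$pixels$bin1] == cm$bins$chrom[cm$pixels$bin2]
    d <- cm$pixels$bin2 - cm$pixels$bin1
    cm$pixels <- cm$pixels[!(intra & d < drop_diagonals), ]
  }
  marg <- marginals(cm, norm = FALSE)
  marg[is.na(marg)] <- 0
  cutoff <- 0
  if (!is.null(coverage)) cutoff <- coverage
  if (!is.null(coverage_fraction)) {
    cutoff <- coverage_fraction * median(marg[marg > 0])
  }
  cm$mask <- cm$mask & marg > 0 & marg >= cutoff
  cm$bias[!cm$mask] <- 0
  cm
}

# Knight-Ruiz balancing of a dense symmetric non-negative matrix with
# strictly positive row sums. Returns x with diag(x) A diag(x) doubly
# stochastic. Direct implementation of the inner-outer Newton iteration
# with conjugate-gradient inner solves.
.kr_vector <- function(A, tol = 1e-10, max_iter = 1000) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  delta <- 0.1; Delta <- 3
  g <- 0.9; etamax <- 0.1
  eta <- etamax
  rt <- tol^2
  v <- x * (A %*% x)[, 1]
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  MVP <- 0
  while (rout > rt && MVP < max_iter) {
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- NA
    Z <- p <- ap <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * (A %*% (x * p))[, 1] + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > n) break
    }
    x <- x * y
    v <- x * (A %*% x)[, 1]
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    MVP <- MVP + k + 1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta; eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), 0.5 * tol / res_norm)
  }
  if (rout > rt) return(NULL)
  as.numeric(x)
}

# ICE / Sinkhorn balancing: iterate x <- x / sqrt(rowsum) until unit rows.
.ice_vector <- function(A, tol = 1e-10, max_iter = 5000) {
  n <- nrow(A)
  x <- rep(1, n)
  for (it in seq_len(max_iter)) {
    r <- x * (A %*% x)[, 1]
    if (max(abs(r - 1)) < tol) return(x)
    x <- x / sqrt(r)
  }
  NULL
}

#' Balance a contact matrix (Knight-Ruiz or iterative correction)
#'
#' Computes per-bin biases so that every valid bin's normalised marginal is
#' 1, per chromosome by default (set `per_chrom = FALSE` for whole-genome
#' balancing). Masked bins receive bias 0 and are excluded. Raw counts are
#' kept; normalised values are `count * b_i * b_j`.
#'
#' @param cm A `contact_matrix` (apply [matrix_filters()] first).
#' @param method `"kr"` (default) or `"ice"`.
#' @param tol Convergence tolerance on `max |rowsum - 1|` (default 1e-10).
#' @param max_iter Iteration budget per chromosome.
#' @param per_chrom Balance each chromosome separately (default `TRUE`).
#' @return The matrix with `bias` set and `metadata$norm` recorded.
#' @export
balance_matrix <- function(cm, method = c("kr", "ice"), tol = 1e-10,
                           max_iter = 5000, per_chrom = TRUE) {
  method <- match.arg(method)
  if (any(cm$pixels$count < 0)) stop("Negative counts cannot be balanced")
  bias <- rep(0, n_bins(cm))
  groups <- if (per_chrom) split(seq_len(n_bins(cm)), cm$bins$chrom) else
    list(genome = seq_len(n_bins(cm)))
  for (gname in names(groups)) {
    rows <- groups[[gname]]
    valid <- rows[cm$mask[rows]]
    if (length(valid) == 0) next
    A <- .dense_rows(cm, valid)
    # bins with zero marginal inside the valid set cannot be balanced
    zero <- rowSums(A) == 0
    if (any(zero)) { valid <- valid[!zero]; A <- A[!zero, !zero, drop = FALSE] }
    if (length(valid) == 0) next
    if (length(valid) == 1) { bias[valid] <- 1 / sqrt(A[1, 1]); next }
    x <- if (method == "kr") .kr_vector(A, tol = min(tol, 1e-10), max_iter = max_iter)
         else .ice_vector(A, tol = min(tol, 1e-10), max_iter = max_iter)
    if (is.null(x)) {
      # polish / fallback via Sinkhorn from the best current point
      x <- .ice_vector(A, tol = min(tol, 1e-12), max_iter = 10 * max_iter)
    }
    if (is.null(x)) stop("Balancing did not converge for ", gname)
    # polish to machine precision with a few Sinkhorn steps
    for (it in 1:100) {
      r <- x * (A %*% x)[, 1]
      if (max(abs(r - 1)) < 1e-14) break
      x <- x / sqrt(r)
    }
    bias[valid] <- x
  }
  cm$bias <- bias
  cm$mask <- cm$mask & bias > 0
  cm$metadata$norm <- method
  cm$expected <- NULL  # stale after rebalancing
  cm
}

# dense symmetric submatrix over arbitrary bin rows (raw counts)
.dense_rows <- function(cm, rows) {
  n <- length(rows)
  pos <- integer(n_bins(cm)); pos[rows] <- seq_len(n)
  sel <- pos[cm$pixels$bin1] > 0 & pos[cm$pixels$bin2] > 0
  px <- cm$pixels[sel, ]
  A <- matrix(0, n, n)
  i <- pos[px$bin1]; j <- pos[px$bin2]
  A[cbind(i, j)] <- px$count
  A[cbind(j, i)] <- px$count
  A
}

#' Compute and store expected values (distance decay)
#'
#' For each chromosome, `e_c(d)` is the mean normalised value over all valid
#' bin pairs at bin distance `d` (implicit zero pixels included in the
#' denominator). A genome-wide profile pools chromosomes, and the
#' inter-chromosomal expectation is the mean over valid inter-bin pairs.
#' The profile is stored inside the matrix for on-demand O/E transforms.
#'
#' @param cm A `contact_matrix` (normalised or raw).
#' @param norm Use normalised values (default `TRUE`).
#' @return The matrix with `$expected` set: `per_chrom` (named list of
#'   vectors indexed by distance + 1), `genome`, `inter`.
#' @export
expected_values <- function(cm, norm = TRUE) {
  chroms <- unique(cm$bins$chrom)
  b1 <- cm$bins$chrom[cm$pixels$bin1]
  b2 <- cm$bins$chrom[cm$pixels$bin2]
  intra_px <- b1 == b2
  if (!any(intra_px & cm$mask[cm$pixels$bin1] & cm$mask[cm$pixels$bin2])) {
    stop("No valid intra-chromosomal pixels; cannot compute expected values")
  }
  v <- if (norm) cm$pixels$count * cm$bias[cm$pixels$bin1] * cm$bias[cm$pixels$bin2]
       else cm$pixels$count
  per_chrom <- list()
  max_n <- 0
  for (cc in chroms) {
    rows <- .chrom_bins(cm, cc)
    n <- length(rows); max_n <- max(max_n, n)
    validpos <- which(cm$mask[rows])
    # valid pair count at each distance d: number of (i, i+d) with both valid
    cnt <- numeric(n)
    if (length(validpos)) {
      ind <- logical(n); ind[validpos] <- TRUE
      for (d in 0:(n - 1)) {
        cnt[d + 1] <- sum(ind[seq_len(n - d)] & ind[seq_len(n - d) + d])
      }
    }
    sel <- intra_px & b1 == cc
    d <- cm$pixels$bin2[sel] - cm$pixels$bin1[sel]
    vv <- v[sel]
    keep <- cm$mask[cm$pixels$bin1[sel]] & cm$mask[cm$pixels$bin2[sel]]
    sums <- numeric(n)
    if (any(keep)) {
      agg <- tapply(vv[keep], d[keep], sum)
      sums[as.integer(names(agg)) + 1] <- as.numeric(agg)
    }
    e <- ifelse(cnt > 0, sums / cnt, NA_real_)
    per_chrom[[cc]] <- e
    attr(per_chrom[[cc]], "sums") <- sums
    attr(per_chrom[[cc]], "counts") <- cnt
  }
  gsums <- numeric(max_n); gcnt <- numeric(max_n)
  for (cc in chroms) {
    s <- attr(per_chrom[[cc]], "sums"); k <- attr(per_chrom[[cc]], "counts")
    gsums[seq_along(s)] <- gsums[seq_along(s)] + s
    gcnt[seq_along(k)] <- gcnt[seq_along(k)] + k
  }
  genome <- ifelse(gcnt > 0, gsums / gcnt, NA_real_)
  # inter-chromosomal scalar
  inter_sel <- !intra_px & cm$mask[cm$pixels$bin1] & cm$mask[cm$pixels$bin2]
  valid_per_chrom <- vapply(chroms, function(cc) sum(cm$mask[.chrom_bins(cm, cc)]), numeric(1))
  tot_valid <- sum(valid_per_chrom)
  n_inter_pairs <- (tot_valid^2 - sum(valid_per_chrom^2)) / 2
  inter <- if (n_inter_pairs > 0) sum(v[inter_sel]) / n_inter_pairs else NA_real_
  cm$expected <- list(per_chrom = lapply(per_chrom, as.numeric),
                      genome = as.numeric(genome), inter = inter)
  cm
}

.ensure_expected <- function(cm) {
  if (is.null(cm$expected)) cm <- expected_values(cm)
  cm
}

.expected_for <- function(cm, chrom, per_chrom = TRUE) {
  cm <- .ensure_expected(cm)
  if (per_chrom) cm$expected$per_chrom[[chrom]] else
    cm$expected$genome[seq_along(cm$expected$per_chrom[[chrom]])]
}

#' Expected-value profile as a tidy tibble
#' @param cm A `contact_matrix` (profile computed on demand).
#' @return Tibble `chrom` (including `"genome-wide"`), `distance` (bp),
#'   `expected`.
#' @export
expected_profile <- function(cm) {
  cm <- .ensure_expected(cm)
  out <- purrr::imap_dfr(cm$expected$per_chrom, function(e, cc) {
    tibble(chrom = cc, distance = (seq_along(e) - 1) * cm$bin_size, expected = e)
  })
  bind_rows(out, tibble(chrom = "genome-wide",
                        distance = (seq_along(cm$expected$genome) - 1) * cm$bin_size,
                        expected = cm$expected$genome))
}

#' Observed/expected pixel stream
#'
#' Divides each normalised intra-chromosomal pixel by the expected value at
#' its bin distance (per-chromosome profile by default) and each
#' inter-chromosomal pixel by the inter expectation. Pixels touching masked
#' bins are omitted.
#'
#' @param cm A `contact_matrix`.
#' @param log2 Return log2 fold-changes.
#' @param per_chrom Use per-chromosome expected values (default) or the
#'   genome-wide profile.
#' @return Tibble `bin1`, `bin2`, `oe`.
#' @export
oe_pixels <- function(cm, log2 = FALSE, per_chrom = TRUE) {
  cm <- .ensure_expected(cm)
  px <- cm$pixels
  keep <- cm$mask[px$bin1] & cm$mask[px$bin2]
  px <- px[keep, ]
  v <- px$count * cm$bias[px$bin1] * cm$bias[px$bin2]
  c1 <- cm$bins$chrom[px$bin1]; c2 <- cm$bins$chrom[px$bin2]
  ev <- numeric(nrow(px))
  for (cc in unique(c1)) {
    s <- c1 == cc & c2 == cc
    e <- if (per_chrom) cm$expected$per_chrom[[cc]] else cm$expected$genome
    ev[s] <- e[px$bin2[s] - px$bin1[s] + 1L]
  }
  ev[c1 != c2] <- cm$expected$inter
  if (any(is.na(ev) | ev == 0)) {
    bad <- which(is.na(ev) | ev == 0)
    if (any(v[bad] != 0)) stop("Expected value 0/undefined at a distance with non-zero pixels")
  }
  out <- tibble(bin1 = px$bin1, bin2 = px$bin2, oe = v / ev)
  if (log2) out$oe <- base::log2(out$oe)
  out
}
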