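# Aggregate ("pileup") analyses: averaged submatrices over region lists
# (rescaled TAD windows or fixed windows at boundaries) and over region
# pairs (APA-style loop pileups).

# area-weighted rescaling of a (possibly NA-holed) square matrix to n_out
.rescale_matrix <- function(M, n_out) {
  n_in <- nrow(M)
  if (n_in == n_out) return(M)
  # weight of input cell k in output cell u: overlap of [k-1,k) with
  # [u*r, (u+1)*r), r = n_in/n_out
  r <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (u in seq_len(n_out)) {
    lo <- (u - 1) * r; hi <- u * r
    ks <- floor(lo):min(n_in - 1, ceiling(hi) - 1)
    for (k in ks) {
      W[u, k + 1] <- max(0, min(hi, k + 1) - max(lo, k))
    }
  }
  A <- !is.na(M)
  M0 <- M; M0[!A] <- 0
  num <- W %*% M0 %*% t(W)
  den <- W %*% (A * 1) %*% t(W)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

.region_window_matrix <- function(cm, chrom, start, end, value = "log2oe") {
  rows <- which(cm$bins$chrom == chrom & cm$bins$end > start & cm$bins$start < end)
  if (length(rows) == 0) return(NULL)
  M <- .dense_chrom(cm, chrom, what = if (value == "norm") "norm" else "oe")
  loc <- rows - min(.chrom_bins(cm, chrom)) + 1L
  S <- M[loc, loc, drop = FALSE]
  if (value == "log2oe") {
    S[S <= 0] <- NA_real_
    S <- base::log2(S)
  }
  S
}

#' Aggregate contact matrix over a list of regions
#'
#' In `"rescaled"` mode each region is expanded by `expansion` of its own
#' size on each side, the corresponding log2-O/E submatrix is interpolated
#' (area-weighted) to a fixed `pixels x pixels` grid, and grids are averaged
#' cell-wise (the TAD preset: the region occupies the central part of the
#' plot). In `"fixed"` mode a window of `window` bp is centred on each
#' region midpoint with no rescaling (the boundary preset). Minus-strand
#' regions are flipped before averaging unless `orient = FALSE`. Cells with
#' no contributing windows are missing.
#'
#' @param cm A balanced `contact_matrix`.
#' @param regions Region tibble (`chrom`, `start`, `end`, optional
#'   `strand`).
#' @param mode `"rescaled"` (default) or `"fixed"`.
#' @param pixels Output grid size for rescaled mode (default 90).
#' @param expansion Expansion fraction per side in rescaled mode
#'   (default 0.5).
#' @param window Window size in bp for fixed mode.
#' @param value `"log2oe"` (default), `"oe"` or `"norm"`.
#' @param orient Flip minus-strand regions (default `TRUE`).
#' @return List of class `aggregate_result`: `matrix` (mean grid),
#'   `n_contrib` (per-cell contributor counts), `n_regions`, `mode`.
#' @export
aggregate_regions <- function(cm, regions, mode = c("rescaled", "fixed"),
                              pixels = 90, expansion = 0.5, window = NULL,
                              value = c("log2oe", "oe", "norm"), orient = TRUE) {
  mode <- match.arg(mode)
  value <- match.arg(value)
  cm <- .ensure_expected(cm)
  if (mode == "fixed") {
    stopifnot(!is.null(window))
    window <- parse_bp(window)
    k <- floor(window / cm$bin_size / 2)
    pixels <- 2 * k + 1
  }
  acc <- matrix(0, pixels, pixels)
  cnt <- matrix(0, pixels, pixels)
  used <- 0
  for (r in seq_len(nrow(regions))) {
    chrom <- regions$chrom[r]
    if (!chrom %in% cm$bins$chrom) next
    clen <- max(cm$bins$end[cm$bins$chrom == chrom])
    if (mode == "rescaled") {
      size <- regions$end[r] - regions$start[r]
      if (size > clen) { warning("Region ", r, " larger than chromosome; skipped"); next }
      s <- regions$start[r] - expansion * size
      e <- regions$end[r] + expansion * size
    } else {
      mid <- (regions$start[r] + regions$end[r]) / 2
      mid_bin <- floor(mid / cm$bin_size)
      s <- (mid_bin - k) * cm$bin_size
      e <- (mid_bin + k + 1) * cm$bin_size
    }
    if (s < 0 || e > clen) next
    S <- .region_window_matrix(cm, chrom, s, e, value = value)
    if (is.null(S) || nrow(S) == 0) next
    if (mode == "fixed" && nrow(S) != pixels) next
    if (mode == "rescaled") S <- .rescale_matrix(S, pixels)
    if (orient && !is.null(regions[["strand"]]) && identical(regions[["strand"]][r], "-")) {
      S <- S[rev(seq_len(nrow(S))), rev(seq_len(ncol(S)))]
    }
    ok <- !is.na(S)
    acc[ok] <- acc[ok] + S[ok]
    cnt <- cnt + ok
    used <- used + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  structure(list(matrix = out, n_contrib = cnt, n_regions = used, mode = mode,
                 value = value, bin_size = cm$bin_size),
            class = "aggregate_result")
}

#' Aggregate contact matrix over region pairs (APA)
#'
#' Centres a fixed square window on the pixel joining each region pair's
#' midpoints and averages the windows cell-wise. The centre-vs-ring
#' enrichment (centre cell over the mean of the outermost ring) is reported.
#'
#' @param cm A balanced `contact_matrix`.
#' @param pairs Region-pair tibble (`chrom1 start1 end1 chrom2 start2 end2`,
#'   intra-chromosomal), e.g. from [read_bedpe()] or [call_loops()].
#' @param window Window size in bp (default `21 * bin_size`).
#' @param value `"log2oe"` (default), `"oe"` or `"norm"`.
#' @return `aggregate_result` with additional `centre_enrichment`.
#' @export
aggregate_pairs <- function(cm, pairs, window = NULL,
                            value = c("log2oe", "oe", "norm")) {
  value <- match.arg(value)
  cm <- .ensure_expected(cm)
  window <- parse_bp(window %||% (21 * cm$bin_size))
  k <- floor(window / cm$bin_size / 2)
  pixels <- 2 * k + 1
  acc <- matrix(0, pixels, pixels); cnt <- matrix(0, pixels, pixels)
  used <- 0
  for (r in seq_len(nrow(pairs))) {
    if (pairs$chrom1[r] != pairs$chrom2[r]) next
    cc <- pairs$chrom1[r]
    if (!cc %in% cm$bins$chrom) next
    rows <- .chrom_bins(cm, cc)
    n <- length(rows)
    m1 <- (pairs$start1[r] + pairs$end1[r]) / 2
    m2 <- (pairs$start2[r] + pairs$end2[r]) / 2
    i <- floor(min(m1, m2) / cm$bin_size) + 1L
    j <- floor(max(m1, m2) / cm$bin_size) + 1L
    if (i - k < 1 || j + k > n || (j - k) - (i + k) < 1) next  # window exceeds range/diagonal
    M <- .dense_chrom(cm, cc, what = if (value == "norm") "norm" else "oe")
    S <- M[(i - k):(i + k), (j - k):(j + k), drop = FALSE]
    if (value == "log2oe") { S[S <= 0] <- NA_real_; S <- base::log2(S) }
    ok <- !is.na(S)
    acc[ok] <- acc[ok] + S[ok]
    cnt <- cnt + ok
    used <- used + 1
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  ring <- c(out[1, ], out[pixels, ], out[, 1], out[, pixels])
  centre <- out[k + 1, k + 1]
  ce <- if (value == "log2oe") centre - mean(ring, na.rm = TRUE)
        else centre / mean(ring, na.rm = TRUE)
  structure(list(matrix = out, n_contrib = cnt, n_regions = used,
                 mode = "pairs", value = value, bin_size = cm$bin_size,
                 centre_enrichment = ce),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat("<aggregate_result> ", nrow(x$matrix), "x", ncol(x$matrix), " grid over ",
      x$n_regions, " regions (", x$mode, ", ", x$value, ")\n", sep = "")
  if (!is.null(x$centre_enrichment)) {
    cat("  centre-vs-ring enrichment: ", signif(x$centre_enrichment, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Write an aggregate grid as TSV
#' @param agg `aggregate_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregate <- function(agg, path) {
  readr::write_tsv(as_tibble(as.data.frame(agg$matrix), .name_repair = "minimal"),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
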