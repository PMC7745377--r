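# Inter-sample comparisons: difference / fold-change matrices and score
# tracks, and sample-level PCA on filtered pixel vectors.

#' Compare two contact matrices or score tracks
#'
#' `method = "difference"` returns `a - b` (minuend first: positive values
#' mean more contacts/higher score in `a`); `method = "fold_change"`
#' returns `a / b`, optionally log2-transformed, and is missing where the
#' denominator is 0. Matrices must share an identical bin set and
#' normalisation scale; the comparison is computed on normalised values
#' (`oe = TRUE` compares O/E instead). Tracks are compared bin-wise on
#' their common score columns. Results are masked wherever either operand
#' is masked/missing, and a difference matrix/track can be fed to any
#' downstream function (e.g. [call_boundaries()] on an insulation
#' difference track).
#'
#' @param a,b Two `contact_matrix` objects, or two score-track tibbles.
#' @param method `"difference"` (default) or `"fold_change"`.
#' @param log2 log2 the fold-change.
#' @param oe Compare O/E-transformed matrices.
#' @return For matrices: a `contact_matrix` whose pixel `count` holds the
#'   comparison value (bias reset to 1; `metadata$comparison` records the
#'   method). For tracks: a track tibble with compared score columns.
#' @export
compare_samples <- function(a, b, method = c("difference", "fold_change"),
                            log2 = FALSE, oe = FALSE) {
  method <- match.arg(method)
  if (inherits(a, "contact_matrix") && inherits(b, "contact_matrix")) {
    if (nrow(a$bins) != nrow(b$bins)) {
      stop("Bin sets differ (", nrow(a$bins), " vs ", nrow(b$bins), " bins)")
    }
    if (!all(a$bins$chrom == b$bins$chrom & a$bins$start == b$bins$start)) {
      div <- which(a$bins$chrom != b$bins$chrom | a$bins$start != b$bins$start)[1]
      stop("Bin sets differ (first divergent bin: ", div, ")")
    }
    va <- if (oe) { x <- oe_pixels(a); setNames(x$oe, paste(x$bin1, x$bin2)) } else {
      setNames(a$pixels$count * a$bias[a$pixels$bin1] * a$bias[a$pixels$bin2],
               paste(a$pixels$bin1, a$pixels$bin2))
    }
    vb <- if (oe) { x <- oe_pixels(b); setNames(x$oe, paste(x$bin1, x$bin2)) } else {
      setNames(b$pixels$count * b$bias[b$pixels$bin1] * b$bias[b$pixels$bin2],
               paste(b$pixels$bin1, b$pixels$bin2))
    }
    keys <- union(names(va), names(vb))
    xa <- ifelse(keys %in% names(va), va[keys], 0)
    xb <- ifelse(keys %in% names(vb), vb[keys], 0)
    ij <- do.call(rbind, strsplit(keys, " "))
    bin1 <- as.integer(ij[, 1]); bin2 <- as.integer(ij[, 2])
    val <- if (method == "difference") xa - xb else {
      fc <- ifelse(xb == 0, NA_real_, xa / xb)
      if (log2) base::log2(fc) else fc
    }
    mask <- a$mask & b$mask
    keep <- mask[bin1] & mask[bin2] & !is.na(val)
    bins <- a$bins
    bins <- .set_chrom_lengths(bins, a$chrom_lengths)
    attr(bins, "bin_size") <- a$bin_size
    # comparison values may legitimately be negative; bypass the count check
    out <- contact_matrix(tibble(bin1 = bin1[keep], bin2 = bin2[keep],
                                 count = abs(val[keep])), bins,
                          mask = mask,
                          metadata = list(comparison = method,
                                          operands = "a_minus_b"))
    signed <- tibble(bin1 = bin1[keep], bin2 = bin2[keep], count = val[keep]) |>
      arrange(.data$bin1, .data$bin2)
    out$pixels <- signed
    return(out)
  }
  # score tracks
  common <- intersect(grep("^score_", names(a), value = TRUE),
                      grep("^score_", names(b), value = TRUE))
  if (length(common) == 0) {
    sca <- setdiff(names(a), c("chrom", "start", "end", "bin_id"))
    scb <- setdiff(names(b), c("chrom", "start", "end", "bin_id"))
    common <- intersect(sca, scb)
  }
  key <- c("chrom", "start", "end")
  m <- inner_join(a[, c(key, intersect("bin_id", names(a)), common)],
                  b[, c(key, common)], by = key, suffix = c("_a", "_b"))
  out <- m[, c(key, intersect("bin_id", names(m)))]
  for (cc in common) {
    xa <- m[[paste0(cc, "_a")]]; xb <- m[[paste0(cc, "_b")]]
    out[[cc]] <- if (method == "difference") xa - xb else {
      fc <- ifelse(xb == 0, NA_real_, xa / xb)
      if (log2) base::log2(fc) else fc
    }
  }
  attr(out, "track_type") <- paste0(method, "_track")
  out
}

#' Sample-level PCA on contact-matrix pixels
#'
#' Each sample's filtered pixel vector (O/E by default) is one observation;
#' features are centred across samples and decomposed by SVD. Pixel filters
#' keep only the most informative contacts: intra-chromosomal pixels within
#' a genomic distance band by default, optionally restricted to the top-k
#' features by cross-sample variance or by mean value.
#'
#' @param samples Named list of `contact_matrix` objects on a shared bin
#'   set (>= 2).
#' @param oe Use O/E values (default `TRUE`) or normalised counts.
#' @param intra_only Keep intra-chromosomal pixels only (default `TRUE`).
#' @param min_distance,max_distance Genomic distance band in bp
#'   (defaults 1e5 and 1e7).
#' @param top_variance Keep only this many features with the largest
#'   cross-sample variance (optional).
#' @param top_value Keep only this many features with the largest mean value
#'   (optional; applied before the variance filter).
#' @param n_components Number of components to return (default 2).
#' @return List of class `pca_result`: `coordinates` (tibble sample x PCs),
#'   `explained_variance`, `n_features`, `filters`.
#' @export
matrix_pca <- function(samples, oe = TRUE, intra_only = TRUE,
                       min_distance = 1e5, max_distance = 1e7,
                       top_variance = NULL, top_value = NULL,
                       n_components = 2) {
  stopifnot(length(samples) >= 2)
  if (is.null(names(samples))) names(samples) <- paste0("sample_", seq_along(samples))
  ref <- samples[[1]]
  vecs <- lapply(samples, function(cm) {
    x <- if (oe) { p <- oe_pixels(cm); setNames(p$oe, paste(p$bin1, p$bin2)) } else {
      setNames(cm$pixels$count * cm$bias[cm$pixels$bin1] * cm$bias[cm$pixels$bin2],
               paste(cm$pixels$bin1, cm$pixels$bin2))
    }
    x
  })
  keys <- Reduce(union, lapply(vecs, names))
  ij <- do.call(rbind, strsplit(keys, " "))
  bin1 <- as.integer(ij[, 1]); bin2 <- as.integer(ij[, 2])
  keep <- rep(TRUE, length(keys))
  same_chrom <- ref$bins$chrom[bin1] == ref$bins$chrom[bin2]
  if (intra_only) keep <- keep & same_chrom
  d_bp <- (bin2 - bin1) * ref$bin_size
  keep <- keep & (!same_chrom | (d_bp >= min_distance & d_bp <= max_distance))
  keys <- keys[keep]
  X <- do.call(rbind, lapply(vecs, function(v) {
    out <- numeric(length(keys))
    hit <- keys %in% names(v)
    out[hit] <- v[keys[hit]]
    out
  }))
  if (!is.null(top_value)) {
    ord <- order(colMeans(X), decreasing = TRUE)
    X <- X[, head(ord, top_value), drop = FALSE]
  }
  if (!is.null(top_variance)) {
    vr <- apply(X, 2, stats::var)
    X <- X[, head(order(vr, decreasing = TRUE), top_variance), drop = FALSE]
  }
  if (ncol(X) < 2) stop("Fewer than 2 pixels survive the filters")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  coords <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  coords <- bind_cols(tibble(sample = names(samples)), coords)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(coordinates = coords,
                 explained_variance = ev[seq_len(k)],
                 n_features = ncol(X),
                 filters = list(oe = oe, intra_only = intra_only,
                                min_distance = min_distance,
                                max_distance = max_distance,
                                top_variance = top_variance,
                                top_value = top_value)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$coordinates), " samples, ", x$n_features,
      " pixel features\n  explained variance: ",
      paste(signif(x$explained_variance, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}
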