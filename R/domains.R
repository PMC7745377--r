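# TAD-scale analyses: insulation score, directionality index and boundary
# calling. Score tracks are tibbles with one column per window size, named
# "score_<bp>".

.window_bins <- function(cm, window_bp) {
  w <- floor(window_bp / cm$bin_size)
  if (w < 1) stop("Window ", window_bp, " bp is smaller than one bin (",
                  cm$bin_size, " bp)")
  w
}

#' Insulation score
#'
#' For each bin i and window of w bins, the raw score is the mean normalised
#' contact value in the off-diagonal square `[i-w, i) x (i, i+w]`. The final
#' score is `log2(raw / normaliser)` with the normaliser the per-chromosome
#' arithmetic mean (default) or geometric mean of the defined raw scores.
#' Windows that cross a chromosome end, or whose square is more than half
#' masked, are missing (masked cells can instead be imputed from the
#' expected profile with `impute = TRUE`).
#'
#' @param cm A balanced `contact_matrix`.
#' @param windows Window sizes in bp (each floored to whole bins, >= 2 bins).
#' @param normalisation `"arithmetic"` (default) or `"geometric"` chromosome
#'   normaliser.
#' @param impute Replace masked cells by their expected value instead of
#'   dropping windows (default `FALSE`).
#' @return Score-track tibble: `chrom`, `start`, `end`, `bin_id`, one
#'   `score_<bp>` column per window.
#' @export
insulation_score <- function(cm, windows,
                             normalisation = c("arithmetic", "geometric"),
                             impute = FALSE) {
  normalisation <- match.arg(normalisation)
  windows <- parse_bp(windows)
  out <- cm$bins
  for (wbp in windows) {
    w <- .window_bins(cm, wbp)
    if (w < 2) stop("Insulation window must span at least 2 bins")
    col <- rep(NA_real_, n_bins(cm))
    for (cc in unique(cm$bins$chrom)) {
      rows <- .chrom_bins(cm, cc)
      n <- length(rows)
      M <- .dense_chrom(cm, cc, what = "norm")
      if (impute) {
        e <- .expected_for(cm, cc)
        D <- abs(outer(seq_len(n), seq_len(n), "-"))
        M[is.na(M)] <- e[D[is.na(M)] + 1L]
      }
      raw <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        if (i - w < 1 || i + w > n) next
        sq <- M[(i - w):(i - 1), (i + 1):(i + w), drop = FALSE]
        if (mean(is.na(sq)) > 0.5) next
        raw[i] <- mean(sq, na.rm = TRUE)
      }
      defined <- !is.na(raw) & raw > 0
      normaliser <- if (normalisation == "geometric") {
        exp(mean(log(raw[defined])))
      } else {
        mean(raw[!is.na(raw)])
      }
      sc <- rep(NA_real_, n)
      sc[defined] <- base::log2(raw[defined] / normaliser)
      col[rows] <- sc
    }
    out[[paste0("score_", format(wbp, scientific = FALSE))]] <- col
  }
  attr(out, "bin_size") <- cm$bin_size
  attr(out, "track_type") <- "insulation"
  out
}

#' Directionality index
#'
#' For bin i with upstream contact sum A (to bins `[i-w, i)`) and downstream
#' sum B (to `(i, i+w]`), `E = (A+B)/2` and
#' `DI = sign(B-A) * ((A-E)^2/E + (B-E)^2/E)`; 0 when `A = B` or `E = 0`.
#' Windows crossing chromosome ends are missing.
#'
#' @inheritParams insulation_score
#' @return Score-track tibble, one `score_<bp>` column per window.
#' @export
directionality_index <- function(cm, windows) {
  windows <- parse_bp(windows)
  out <- cm$bins
  for (wbp in windows) {
    w <- .window_bins(cm, wbp)
    col <- rep(NA_real_, n_bins(cm))
    for (cc in unique(cm$bins$chrom)) {
      rows <- .chrom_bins(cm, cc)
      n <- length(rows)
      M <- .dense_chrom(cm, cc, what = "norm")
      for (i in seq_len(n)) {
        if (i - w < 1 || i + w > n) next
        A <- sum(M[i, (i - w):(i - 1)], na.rm = TRUE)
        B <- sum(M[i, (i + 1):(i + w)], na.rm = TRUE)
        E <- (A + B) / 2
        col[rows[i]] <- if (E == 0 || A == B) 0 else
          sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
      }
    }
    out[[paste0("score_", format(wbp, scientific = FALSE))]] <- col
  }
  attr(out, "bin_size") <- cm$bin_size
  attr(out, "track_type") <- "directionality"
  out
}

# local minima of a gap-free numeric segment; plateaus collapse to the
# central index (left of centre on even plateaus)
.local_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  mins <- integer(0)
  for (k in seq_along(runs$values)) {
    left_ok <- k > 1 && runs$values[k - 1] > runs$values[k]
    right_ok <- k < length(runs$values) && runs$values[k + 1] > runs$values[k]
    if (left_ok && right_ok) {
      mins <- c(mins, starts[k] + floor((runs$lengths[k] - 1) / 2))
    }
  }
  mins
}

.local_maxima <- function(x) .local_minima(-x)

#' Call insulating boundaries from a score track
#'
#' Boundaries are local minima of the insulation (or difference) track. The
#' track is split at missing-value runs; extrema never bridge gaps. For each
#' minimum the nearest local maxima to the left and right are found and the
#' boundary score is the mean of the two deltas (`min_of_deltas = TRUE`
#' takes the smaller delta instead). Boundaries with score >= `min_score`
#' are returned.
#'
#' @param track Score-track tibble (e.g. from [insulation_score()] or a
#'   track comparison).
#' @param window Which `score_<bp>` column to use (bp value or full column
#'   name); defaults to the only score column.
#' @param min_score Minimum boundary strength (default 1.0).
#' @param min_of_deltas Combine the two flanking deltas with `min()` instead
#'   of the mean.
#' @return Tibble `chrom`, `start`, `end`, `bin_id`, `score`, sorted by
#'   position.
#' @export
call_boundaries <- function(track, window = NULL, min_score = 1.0,
                            min_of_deltas = FALSE) {
  score_cols <- grep("^score_", names(track), value = TRUE)
  col <- if (is.null(window)) {
    if (length(score_cols) != 1) stop("Several score columns; specify `window`")
    score_cols
  } else if (as.character(window) %in% names(track)) {
    as.character(window)
  } else {
    paste0("score_", format(parse_bp(window), scientific = FALSE))
  }
  if (!col %in% names(track)) stop("No score column '", col, "' in track")
  x <- track[[col]]
  if (all(is.na(x))) {
    warning("Score track entirely missing; no boundaries")
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  bin_id = integer(), score = numeric()))
  }
  res <- list()
  for (cc in unique(track$chrom)) {
    rows <- which(track$chrom == cc)
    xs <- x[rows]
    # segments between missing runs
    seg_id <- cumsum(is.na(xs))
    for (s in split(seq_along(xs)[!is.na(xs)], seg_id[!is.na(xs)])) {
      if (length(s) < 3 || any(diff(s) != 1)) next
      seg <- xs[s]
      mins <- .local_minima(seg)
      maxs <- .local_maxima(seg)
      for (m in mins) {
        lm <- maxs[maxs < m]; rm_ <- maxs[maxs > m]
        left_val <- if (length(lm)) seg[max(lm)] else max(seg[1:m])
        right_val <- if (length(rm_)) seg[min(rm_)] else max(seg[m:length(seg)])
        deltas <- c(left_val - seg[m], right_val - seg[m])
        sc <- if (min_of_deltas) min(deltas) else mean(deltas)
        res[[length(res) + 1]] <- tibble(
          chrom = cc, start = track$start[rows[s[m]]], end = track$end[rows[s[m]]],
          bin_id = track$bin_id[rows[s[m]]], score = sc)
      }
    }
  }
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  bin_id = integer(), score = numeric()))
  }
  out <- out[out$score >= min_score, ]
  arrange(out, match(.data$chrom, unique(track$chrom)), .data$start)
}
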