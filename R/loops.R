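# Local-neighbourhood Poisson loop caller. For each intra-chromosomal pixel
# (i, j) sufficiently far from the diagonal, the local expectation is
# estimated from four neighbourhoods (donut, lower-left, horizontal,
# vertical) on the raw-count scale:
#   lambda_n(i,j) = [sum raw counts in n] / [sum model values in n] * model(i,j)
# where model(a,b) = e(|a-b|) / (b_a * b_b) is the distance-decay
# expectation carried back to raw scale through the bias vector. Observed
# integer counts are tested against Poisson(lambda_n); p-values are
# BH-corrected within lambda chunks (powers of 2^(1/3)).

.nbhd_masks <- function(p, w) {
  # relative offsets (da, db) for each neighbourhood around (i, j)
  grid <- expand.grid(da = -w:w, db = -w:w)
  peak <- abs(grid$da) <= p & abs(grid$db) <= p
  donut <- !peak & grid$da != 0 & grid$db != 0
  lower_left <- grid$da >= 1 & grid$da <= w & grid$db >= -w & grid$db <= -1 & !peak
  horizontal <- abs(grid$da) <= 1 & !(abs(grid$db) <= p)
  vertical <- abs(grid$db) <= 1 & !(abs(grid$da) <= p)
  list(donut = grid[donut, ], lower_left = grid[lower_left, ],
       horizontal = grid[horizontal, ], vertical = grid[vertical, ])
}

# single-linkage components under Chebyshev distance <= md, per chromosome;
# only pixels in neighbouring md-sized grid cells are compared
.cluster_pixels <- function(chrom, i, j, md) {
  k <- length(i)
  parent <- seq_len(k)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  cell <- paste(chrom, i %/% md, j %/% md)
  buckets <- split(seq_len(k), cell)
  ci <- i %/% md; cj <- j %/% md
  for (a in seq_len(k)) {
    for (da in -1:1) for (db in -1:1) {
      key <- paste(chrom[a], ci[a] + da, cj[a] + db)
      for (b in buckets[[key]]) {
        if (b >= a) next
        if (chrom[b] == chrom[a] &&
            max(abs(i[a] - i[b]), abs(j[a] - j[b])) <= md) {
          ra <- find(a); rb <- find(b)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  match(roots, unique(roots))
}

# S[i,j] = sum over offsets of M[i+da, j+db], out-of-range cells contribute 0
.offset_sum <- function(M, off) {
  n <- nrow(M)
  S <- matrix(0, n, n)
  for (k in seq_len(nrow(off))) {
    da <- off$da[k]; db <- off$db[k]
    ri <- max(1, 1 - da):min(n, n - da)
    ci <- max(1, 1 - db):min(n, n - db)
    S[ri, ci] <- S[ri, ci] + M[ri + da, ci + db]
  }
  S
}

.lambda_chunk <- function(lambda) {
  # chunk k holds lambdas in [2^((k-1)/3), 2^(k/3)); lambdas <= 1 share chunk 0
  chunk <- integer(length(lambda))
  pos <- !is.na(lambda) & lambda > 1
  chunk[pos] <- as.integer(ceiling(3 * log2(lambda[pos])))
  chunk[is.na(lambda)] <- NA_integer_
  chunk
}

#' Call chromatin loops (donut-neighbourhood Poisson test)
#'
#' @param cm A balanced `contact_matrix` with (or able to compute) expected
#'   values.
#' @param p Peak radius in bins (default 2).
#' @param w Neighbourhood radius in bins (default 5, must exceed `p`).
#' @param fdr q-value threshold applied to every neighbourhood
#'   (default 0.1); may be a named vector
#'   `c(donut=, lower_left=, horizontal=, vertical=)`.
#' @param enrichment O/E-enrichment thresholds per neighbourhood
#'   (defaults: donut and lower-left 1.75, horizontal and vertical 1.5).
#' @param merge_distance Cluster distance in bp for merging adjacent
#'   significant pixels (default `3 * bin_size`).
#' @param min_offset Minimum diagonal offset in bins (default `w + p`).
#' @param singleton_fdr Single-pixel clusters are kept only when all four
#'   q-values fall below this stricter threshold (default 0.02); isolated
#'   pixels of borderline significance are the classic false-positive mode
#'   of local-neighbourhood callers. Set to `fdr` to disable.
#' @return A tibble of class `loop_calls`: one row per significant pixel
#'   with observed count, per-neighbourhood expected counts, enrichments and
#'   q-values, plus `cluster` id and cluster-centroid coordinates.
#' @export
call_loops <- function(cm, p = 2, w = 5, fdr = 0.1,
                       enrichment = c(donut = 1.75, lower_left = 1.75,
                                      horizontal = 1.5, vertical = 1.5),
                       merge_distance = NULL, min_offset = NULL,
                       singleton_fdr = 0.02) {
  if (w <= p) stop("Neighbourhood radius w must exceed peak radius p")
  if (is.null(cm$metadata$norm)) stop("Loop calling requires a balanced matrix")
  cm <- .ensure_expected(cm)
  nb <- c("donut", "lower_left", "horizontal", "vertical")
  if (length(fdr) == 1) fdr <- setNames(rep(fdr, 4), nb)
  merge_distance <- merge_distance %||% (3 * cm$bin_size)
  min_offset <- min_offset %||% (w + p)
  masks <- .nbhd_masks(p, w)

  all_pix <- list()
  for (cc in unique(cm$bins$chrom)) {
    rows <- .chrom_bins(cm, cc)
    n <- length(rows)
    if (n < 2 * w + 2) next
    Raw <- .dense_chrom(cm, cc, what = "count", keep_masked_na = TRUE)
    e <- .expected_for(cm, cc)
    bias <- cm$bias[rows]
    D <- abs(outer(seq_len(n), seq_len(n), "-"))
    Model <- e[D + 1L] / outer(bias, bias)
    Model[!is.finite(Model)] <- NA_real_
    bad <- !cm$mask[rows]
    Model[bad, ] <- NA_real_; Model[, bad] <- NA_real_

    cand <- which(!is.na(Raw) & Raw > 0 & D >= min_offset, arr.ind = TRUE)
    cand <- cand[cand[, 2] > cand[, 1], , drop = FALSE]
    # complete neighbourhoods only: w bins inside matrix and off-diagonal
    keep <- cand[, 1] - w >= 1 & cand[, 2] + w <= n &
      (cand[, 2] - cand[, 1]) > w
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    res <- tibble(chrom = cc, i = rows[cand[, 1]], j = rows[cand[, 2]],
                  observed = Raw[cand])
    Raw0 <- Raw; Raw0[is.na(Raw0)] <- 0
    Mod0 <- Model; Mod0[is.na(Mod0)] <- 0
    for (nm in nb) {
      S_obs <- .offset_sum(Raw0, masks[[nm]])
      S_mod <- .offset_sum(Mod0, masks[[nm]])
      lam <- (S_obs[cand] / S_mod[cand]) * Model[cand]
      lam[S_mod[cand] == 0] <- NA_real_
      res[[paste0("expected_", nm)]] <- lam
      res[[paste0("oe_", nm)]] <- res$observed / lam
      res[[paste0("p_", nm)]] <- ppois(res$observed - 1, lam, lower.tail = FALSE)
    }
    all_pix[[cc]] <- res
  }
  out <- bind_rows(all_pix)
  if (nrow(out) == 0) {
    return(structure(tibble(), class = c("loop_calls", "tbl_df", "tbl", "data.frame")))
  }
  out <- out[stats::complete.cases(out[paste0("expected_", nb)]), ]
  # lambda-chunked BH within each neighbourhood
  for (nm in nb) {
    chunk <- .lambda_chunk(out[[paste0("expected_", nm)]])
    q <- rep(NA_real_, nrow(out))
    for (ch in unique(chunk)) {
      s <- chunk == ch
      q[s] <- p.adjust(out[[paste0("p_", nm)]][s], method = "BH")
    }
    out[[paste0("q_", nm)]] <- q
  }
  pass <- rep(TRUE, nrow(out))
  for (nm in nb) {
    pass <- pass & out[[paste0("q_", nm)]] <= fdr[[nm]] &
      out[[paste0("oe_", nm)]] >= enrichment[[nm]]
  }
  calls <- out[pass, ]
  calls <- arrange(calls, .data$chrom, .data$i, .data$j)
  # single-linkage clustering by Chebyshev bin distance (bucketed union-find)
  if (nrow(calls) > 0) {
    md_bins <- ceiling(merge_distance / cm$bin_size)
    calls$cluster <- .cluster_pixels(calls$chrom, calls$i, calls$j, md_bins)
    calls <- calls |>
      group_by(.data$cluster) |>
      mutate(centroid_i = round(mean(.data$i)), centroid_j = round(mean(.data$j)),
             cluster_size = n()) |>
      ungroup()
    # singleton post-filter: lone pixels must clear the stricter threshold
    qmax <- do.call(pmax, calls[paste0("q_", nb)])
    keep <- calls$cluster_size > 1 | qmax <= singleton_fdr
    calls <- calls[keep, ]
    calls$cluster <- match(calls$cluster, unique(calls$cluster))
    b1 <- cm$bins[calls$i, ]; b2 <- cm$bins[calls$j, ]
    calls <- bind_cols(
      tibble(chrom1 = b1$chrom, start1 = b1$start, end1 = b1$end,
             chrom2 = b2$chrom, start2 = b2$start, end2 = b2$end),
      calls[, setdiff(names(calls), "chrom")])
  }
  structure(calls, class = c("loop_calls", class(tibble())))
}

#' Write loop calls as BEDPE
#' @param loops `loop_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  extra <- intersect(c("observed", paste0("q_", c("donut", "lower_left",
                                                  "horizontal", "vertical")),
                       "cluster"), names(loops))
  readr::write_tsv(as_tibble(loops)[, c(cols, extra)], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BEDPE file of region pairs
#' @param path Input path.
#' @return Tibble `chrom1 start1 end1 chrom2 start2 end2` (+ extra columns).
#' @export
read_bedpe <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  out <- tibble(chrom1 = as.character(tab[[1]]), start1 = as.numeric(tab[[2]]),
                end1 = as.numeric(tab[[3]]), chrom2 = as.character(tab[[4]]),
                start2 = as.numeric(tab[[5]]), end2 = as.numeric(tab[[6]]))
  out
}
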