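# broom-style tidiers for the package's result objects.

#' Tidy a contact matrix into a pixel tibble
#'
#' @param x A `contact_matrix`.
#' @param norm Include the normalised value column.
#' @param ... Unused.
#' @return Tibble with genomic coordinates of both bins, `count` and
#'   (optionally) `norm`.
#' @export
tidy.contact_matrix <- function(x, norm = TRUE, ...) {
  b1 <- x$bins[x$pixels$bin1, ]
  b2 <- x$bins[x$pixels$bin2, ]
  out <- tibble(chrom1 = b1$chrom, start1 = b1$start, end1 = b1$end,
                chrom2 = b2$chrom, start2 = b2$start, end2 = b2$end,
                bin1 = x$pixels$bin1, bin2 = x$pixels$bin2,
                count = x$pixels$count)
  if (norm) out$norm <- x$pixels$count * x$bias[x$pixels$bin1] * x$bias[x$pixels$bin2]
  out
}

#' One-row summary of a contact matrix
#' @inheritParams tidy.contact_matrix
#' @return One-row tibble: bin/pixel counts, total contacts, valid-bin
#'   fraction, normalisation method.
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble(n_bins = nrow(x$bins), n_valid_bins = sum(x$mask),
         n_pixels = nrow(x$pixels), total_contacts = sum(x$pixels$count),
         bin_size = x$bin_size, norm = x$metadata$norm %||% "none",
         has_expected = !is.null(x$expected))
}

#' Tidy a saddle profile into long format
#' @param x A `saddle_result`.
#' @param ... Unused.
#' @return Tibble `group1`, `group2`, `mean_oe`, plus per-group `ev1`/`ev2`.
#' @export
tidy.saddle_result <- function(x, ...) {
  G <- nrow(x$saddle)
  out <- tidyr::expand_grid(group1 = seq_len(G), group2 = seq_len(G))
  out$mean_oe <- x$saddle[cbind(out$group1, out$group2)]
  out$ev1 <- x$group_ev[out$group1]
  out$ev2 <- x$group_ev[out$group2]
  out
}

#' @export
glance.saddle_result <- function(x, ...) {
  tibble(n_groups = nrow(x$saddle), log2 = isTRUE(x$log2),
         strength = tryCatch(compartment_strength(x), error = function(e) NA_real_))
}

#' Tidy PCA sample coordinates
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return The per-sample coordinate tibble.
#' @export
tidy.pca_result <- function(x, ...) x$coordinates

#' @export
glance.pca_result <- function(x, ...) {
  tibble(n_samples = nrow(x$coordinates), n_features = x$n_features,
         pc1_variance = x$explained_variance[1],
         pc2_variance = x$explained_variance[2] %||% NA_real_)
}

#' Tidy an aggregate grid into long format
#' @param x An `aggregate_result`.
#' @param ... Unused.
#' @return Tibble `row`, `col`, `value`, `n_contrib`.
#' @export
tidy.aggregate_result <- function(x, ...) {
  n <- nrow(x$matrix)
  out <- tidyr::expand_grid(row = seq_len(n), col = seq_len(n))
  out$value <- x$matrix[cbind(out$row, out$col)]
  out$n_contrib <- x$n_contrib[cbind(out$row, out$col)]
  out
}

#' @export
glance.aggregate_result <- function(x, ...) {
  tibble(grid = nrow(x$matrix), n_regions = x$n_regions, mode = x$mode,
         centre_enrichment = x$centre_enrichment %||% NA_real_)
}
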