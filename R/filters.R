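# The read-pair filter suite. Filters are evaluated in a fixed, documented
# order and each removed pair is attributed to the FIRST failing filter;
# the full set of failures is kept as logical columns for inspection.

.filter_order <- c("unmapped", "multimapping", "mapq", "self_ligation",
                   "pcr_duplicate", "ligation_error", "insert_size",
                   "read_density", "custom")

#' Default pair-filter configuration
#'
#' @param min_mapq Minimum mapping quality (default 3).
#' @param le_inward_cutoff Inward pairs closer than this (bp, restriction-site
#'   separation) are treated as uncut/re-ligation artefacts (default 5000).
#' @param le_outward_cutoff Same for outward pairs (default 5000).
#' @param max_insert_size Maximum sum of the two mates' restriction-site
#'   distances (bp); pairs above it are unexpected-insert-size artefacts
#'   (default 10000).
#' @param density_quantile Fragments whose pair count strictly exceeds this
#'   quantile of per-fragment counts have all their pairs removed
#'   (default 0.9999).
#' @param filter_self_ligations,filter_duplicates Toggle those filters.
#' @param custom Optional function `f(pairs) -> logical` marking pairs to
#'   remove (registered custom predicate).
#' @return Config list for [filter_pairs()].
#' @export
pair_filter_config <- function(min_mapq = 3, le_inward_cutoff = 5000,
                               le_outward_cutoff = 5000,
                               max_insert_size = 10000,
                               density_quantile = 0.9999,
                               filter_self_ligations = TRUE,
                               filter_duplicates = TRUE,
                               custom = NULL) {
  if (min_mapq < 0 || le_inward_cutoff < 0 || le_outward_cutoff < 0 ||
      (!is.null(max_insert_size) && max_insert_size < 0)) {
    stop("Filter cutoffs must be non-negative")
  }
  list(min_mapq = min_mapq, le_inward_cutoff = le_inward_cutoff,
       le_outward_cutoff = le_outward_cutoff, max_insert_size = max_insert_size,
       density_quantile = density_quantile,
       filter_self_ligations = filter_self_ligations,
       filter_duplicates = filter_duplicates, custom = custom)
}

#' Filter assigned read pairs for Hi-C artefacts
#'
#' Applies, in order: (1) unmapped mate; (2) multimapping mate; (3) mapping
#' quality below `min_mapq`; (4) self-ligation (both mates on one fragment);
#' (5) PCR duplicate (both mates identical in chromosome, position and
#' strand; first occurrence kept); (6) ligation error (inward/outward pairs
#' with restriction-site separation below the cutoffs); (7) unexpected insert
#' size (sum of restriction-site distances above `max_insert_size`);
#' (8) unusual read density (all pairs of fragments whose count exceeds a
#' high quantile); then any custom predicate. Inter-chromosomal pairs are
#' exempt from the self-ligation, ligation-error and insert-size filters.
#'
#' @param pairs Pair tibble from [assign_pairs()].
#' @param config Configuration from [pair_filter_config()].
#' @return List with `pairs` (the surviving pairs), `removed` (removed pairs
#'   with their attributed filter in `filtered_by`), and `stats` (per-filter
#'   counts tibble; `total = valid + sum(removed)`).
#' @export
filter_pairs <- function(pairs, config = pair_filter_config()) {
  p <- pairs
  n <- nrow(p)
  intra <- !is.na(p$separation)

  fail <- tibble(
    unmapped = (p[["unmapped1"]] %||% rep(FALSE, n)) | (p[["unmapped2"]] %||% rep(FALSE, n)) |
      (p[["unmappable"]] %||% rep(FALSE, n)),
    multimapping = (p[["multimap1"]] %||% rep(FALSE, n)) | (p[["multimap2"]] %||% rep(FALSE, n)),
    mapq = p$mapq1 < config$min_mapq | p$mapq2 < config$min_mapq,
    self_ligation = config$filter_self_ligations & intra &
      !is.na(p$frag1) & p$frag1 == p$frag2,
    pcr_duplicate = if (config$filter_duplicates) {
      duplicated(paste(p$chrom1, p$pos1, p$strand1, p$chrom2, p$pos2, p$strand2))
    } else rep(FALSE, n),
    ligation_error = intra &
      ((p$orientation == "inward" & p$separation < config$le_inward_cutoff) |
       (p$orientation == "outward" & p$separation < config$le_outward_cutoff)),
    insert_size = if (is.null(config$max_insert_size)) rep(FALSE, n) else {
      intra & !is.na(p$rsd1) & (p$rsd1 + p$rsd2) > config$max_insert_size
    }
  )
  # read-density filter: per-fragment pair counts over pairs still unexplained
  frag_counts <- table(c(p$frag1, p$frag2))
  if (length(frag_counts)) {
    # empirical (type 1) quantile: with the heavy ties of integer counts the
    # cutoff sits at the maximum unless a fragment is a genuine outlier
    cutoff <- quantile(as.numeric(frag_counts), config$density_quantile,
                       names = FALSE, type = 1)
    hot <- as.integer(names(frag_counts)[as.numeric(frag_counts) > cutoff])
    fail$read_density <- (!is.na(p$frag1) & p$frag1 %in% hot) |
      (!is.na(p$frag2) & p$frag2 %in% hot)
  } else {
    fail$read_density <- rep(FALSE, n)
  }
  fail$custom <- if (is.null(config$custom)) rep(FALSE, n) else config$custom(p)
  fail[is.na(fail)] <- FALSE

  fm <- as.matrix(fail[, .filter_order])
  first_fail <- apply(fm, 1, function(r) if (any(r)) .filter_order[which(r)[1]] else NA_character_)
  valid <- is.na(first_fail)

  stats <- tibble(filter = .filter_order,
                  removed = unname(vapply(.filter_order,
                                   function(f) sum(first_fail == f, na.rm = TRUE), numeric(1))))
  stats <- bind_rows(stats,
                     tibble(filter = c("valid", "total"),
                            removed = c(sum(valid), n)))
  removed <- p[!valid, ]
  removed$filtered_by <- first_fail[!valid]
  out_pairs <- p[valid, ]
  list(pairs = out_pairs, removed = removed, stats = stats,
       fail_mask = as_tibble(fail))
}

#' Diagnostic statistics for read pairs
#'
#' Computes (a) the ligation-error curves: the fraction of each of the four
#' pair orientations in log-spaced genomic-separation bins, with the 0.25
#' random expectation; (b) the insert-size (sum of restriction-site
#' distances) distribution and its median; (c) per-filter summary counts
#' when a [filter_pairs()] result is supplied.
#'
#' @param pairs Pair tibble from [assign_pairs()] (pre-filter, typically).
#' @param n_bins Number of log-spaced separation bins (default 30).
#' @return List with tibbles `ligation_error` (`sep_mid`, `orientation`,
#'   `fraction`, `n`), `insert_size` (`insert_size`) and scalar
#'   `median_insert_size`.
#' @export
pair_diagnostics <- function(pairs, n_bins = 30) {
  intra <- pairs[!is.na(pairs$separation) & pairs$separation > 0, ]
  if (nrow(intra) == 0) {
    return(list(ligation_error = tibble(sep_mid = numeric(), orientation = character(),
                                        fraction = numeric(), n = integer()),
                insert_size = tibble(insert_size = numeric()),
                median_insert_size = NA_real_))
  }
  lo <- log10(max(1, min(intra$separation)))
  hi <- log10(max(intra$separation) + 1)
  breaks <- 10^seq(lo, hi, length.out = n_bins + 1)
  intra$sep_bin <- cut(intra$separation, breaks = breaks, include.lowest = TRUE)
  le <- intra |>
    dplyr::count(.data$sep_bin, .data$orientation) |>
    group_by(.data$sep_bin) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    tidyr::complete(.data$sep_bin, orientation = c("inward", "outward", "same_fwd", "same_rev"),
                    fill = list(n = 0L, fraction = 0)) |>
    mutate(sep_mid = sqrt(breaks[as.integer(.data$sep_bin)] *
                          breaks[as.integer(.data$sep_bin) + 1L]))
  ins <- tibble(insert_size = intra$rsd1 + intra$rsd2)
  list(ligation_error = le[, c("sep_mid", "orientation", "fraction", "n")],
       insert_size = ins,
       median_insert_size = median(ins$insert_size, na.rm = TRUE))
}
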