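# The contact_matrix S3 class: a sparse, symmetric, binned Hi-C matrix.
# Only the upper triangle (bin1 <= bin2) is stored, as a tibble of raw
# counts. The per-bin bias vector b and valid mask live alongside; the
# normalised value of a pixel is count * b[bin1] * b[bin2], so raw counts
# are never lost (the loop caller needs integers).

#' Construct a contact matrix from pixel triplets
#'
#' @param pixels Tibble with `bin1`, `bin2` (1-based bin ids) and `count`.
#'   Triplets are canonicalised to `bin1 <= bin2` and duplicates summed.
#' @param bins Bin tibble from [make_bins()] (or a fragment tibble for
#'   fragment-level matrices, with `frag_id` renamed to `bin_id`).
#' @param bias Optional per-bin bias vector (default 1; masked bins 0).
#' @param mask Optional logical valid-bin vector (default all valid).
#' @param metadata Named list (resolution, normalisation method, ...).
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(pixels, bins, bias = NULL, mask = NULL, metadata = list()) {
  stopifnot(all(c("bin1", "bin2") %in% names(pixels)))
  if (is.null(pixels[["count"]]) && !is.null(pixels[["value"]])) pixels$count <- pixels[["value"]]
  nb <- nrow(bins)
  if (nrow(pixels) > 0 && (max(pixels$bin1, pixels$bin2) > nb || min(pixels$bin1, pixels$bin2) < 1)) {
    stop("Pixel bin ids outside 1..", nb)
  }
  if (any(pixels$count < 0)) stop("Negative pixel counts are not allowed")
  i <- pmin(pixels$bin1, pixels$bin2)
  j <- pmax(pixels$bin1, pixels$bin2)
  px <- tibble(bin1 = as.integer(i), bin2 = as.integer(j), count = pixels$count) |>
    group_by(.data$bin1, .data$bin2) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$bin1, .data$bin2)
  obj <- structure(list(
    bins = as_tibble(bins[, intersect(c("chrom", "start", "end", "bin_id"), names(bins))]),
    pixels = px,
    bias = bias %||% rep(1, nb),
    mask = mask %||% rep(TRUE, nb),
    expected = NULL,
    chrom_lengths = chrom_lengths(bins),
    bin_size = attr(bins, "bin_size") %||% stats::median(bins$end - bins$start),
    metadata = metadata
  ), class = "contact_matrix")
  obj
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$bins), " bins (",
      length(unique(x$bins$chrom)), " chromosome(s), bin size ",
      format(x$bin_size, scientific = FALSE), " bp), ",
      nrow(x$pixels), " non-zero pixels\n", sep = "")
  cat("  valid bins: ", sum(x$mask), "/", nrow(x$bins),
      "; normalisation: ", x$metadata$norm %||% "none",
      "; expected values: ", if (is.null(x$expected)) "absent" else "stored", "\n", sep = "")
  invisible(x)
}

n_bins <- function(cm) nrow(cm$bins)

.chrom_bins <- function(cm, chrom) which(cm$bins$chrom == chrom)

#' Bin filtered pairs into a contact matrix
#'
#' Each valid pair increments the pixel of the bin pair containing the two
#' fragment midpoints. Several pair sets may be given as a list; their
#' counts are summed (this also serves to merge matrices from multiple
#' lanes/replicates). With `bins = fragments` the result is the
#' fragment-level matrix itself.
#'
#' @param pairs Pair tibble from [assign_pairs()]/[filter_pairs()], or a list
#'   of such tibbles.
#' @param bins Bin tibble from [make_bins()].
#' @param fragments Fragment tibble the pairs were assigned against.
#' @return A raw-count `contact_matrix`.
#' @export
bin_pairs <- function(pairs, bins, fragments) {
  if (is.data.frame(pairs)) pairs <- list(pairs)
  mids <- (fragments$start + fragments$end) / 2
  px <- purrr::map_dfr(pairs, function(p) {
    if (!all(p$chrom1 %in% bins$chrom) || !all(p$chrom2 %in% bins$chrom)) {
      bad <- setdiff(unique(c(p$chrom1, p$chrom2)), unique(bins$chrom))
      stop("Pairs reference chromosome(s) absent from bins: ", paste(bad, collapse = ", "))
    }
    i1 <- locate_region(bins, fragments$chrom[p$frag1], mids[p$frag1])
    i2 <- locate_region(bins, fragments$chrom[p$frag2], mids[p$frag2])
    tibble(bin1 = bins$bin_id[i1], bin2 = bins$bin_id[i2], count = 1)
  })
  contact_matrix(px, bins)
}

#' Per-bin marginals (row sums of the symmetric matrix)
#'
#' @param cm A `contact_matrix`.
#' @param norm Use normalised values (`count * b_i * b_j`)? Default `TRUE`.
#' @return Numeric vector, one value per bin (masked bins `NA`).
#' @export
marginals <- function(cm, norm = TRUE) {
  v <- if (norm) cm$pixels$count * cm$bias[cm$pixels$bin1] * cm$bias[cm$pixels$bin2]
       else cm$pixels$count
  # each off-diagonal pixel contributes to both bins; diagonal once
  m <- numeric(n_bins(cm))
  offdiag <- cm$pixels$bin1 != cm$pixels$bin2
  idx <- c(cm$pixels$bin1, cm$pixels$bin2[offdiag])
  vals <- c(v, v[offdiag])
  agg <- tapply(vals, idx, sum)
  m[as.integer(names(agg))] <- as.numeric(agg)
  m[!cm$mask] <- NA_real_
  m
}

# dense symmetric matrix for one chromosome; what in c("count","norm","oe","log2oe")
.dense_chrom <- function(cm, chrom, what = "norm", keep_masked_na = TRUE) {
  rows <- .chrom_bins(cm, chrom)
  off <- min(rows) - 1L
  n <- length(rows)
  M <- matrix(0, n, n)
  sel <- cm$pixels$bin1 %in% rows & cm$pixels$bin2 %in% rows
  px <- cm$pixels[sel, ]
  v <- px$count
  if (what != "count") v <- v * cm$bias[px$bin1] * cm$bias[px$bin2]
  if (what %in% c("oe", "log2oe")) {
    e <- .expected_for(cm, chrom)
    d <- px$bin2 - px$bin1
    v <- v / e[d + 1L]
  }
  i <- px$bin1 - off
  j <- px$bin2 - off
  M[cbind(i, j)] <- v
  M[cbind(j, i)] <- v
  if (what %in% c("oe", "log2oe")) {
    # zero pixels also have O/E 0; fill implicit zeros explicitly (already 0)
    if (what == "log2oe") M <- log2(M)
  }
  if (keep_masked_na) {
    bad <- which(!cm$mask[rows])
    M[bad, ] <- NA_real_
    M[, bad] <- NA_real_
  }
  dimnames(M) <- list(rows, rows)
  M
}

.parse_region <- function(cm, region) {
  if (is.character(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9eE.+]+)-([0-9eE.+]+)$", region))[[1]]
    if (length(m) == 4) {
      return(list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4])))
    }
    if (region %in% cm$bins$chrom) {
      rows <- .chrom_bins(cm, region)
      return(list(chrom = region, start = 0, end = max(cm$bins$end[rows])))
    }
    stop("Cannot parse region '", region, "'")
  }
  list(chrom = region$chrom[1], start = region$start[1], end = region$end[1])
}

.region_bins <- function(cm, region) {
  r <- .parse_region(cm, region)
  if (!r$chrom %in% cm$bins$chrom) stop("Chromosome '", r$chrom, "' not in matrix")
  rows <- which(cm$bins$chrom == r$chrom & cm$bins$end > r$start & cm$bins$start < r$end)
  if (length(rows) == 0) stop("Region outside genome: ", r$chrom, ":", r$start, "-", r$end)
  rows
}

#' Fetch a dense submatrix
#'
#' Returns the dense, symmetric-completed submatrix for a region (or region
#' pair), with masked rows/columns as `NA`. Values are normalised by
#' default; `oe = TRUE` divides by the distance-matched expected value
#' (intra) or the inter-chromosomal expected scalar.
#'
#' @param cm A `contact_matrix`.
#' @param region1 Region string `"chr:start-end"`, chromosome name, or
#'   one-row tibble.
#' @param region2 Optional second region (default: same as `region1`).
#' @param oe Observed/expected transform (default `FALSE`).
#' @param log2 log2-transform O/E values.
#' @param norm Use normalised counts (default `TRUE`).
#' @return Dense numeric matrix, bin ids as dimnames.
#' @export
fetch <- function(cm, region1, region2 = NULL, oe = FALSE, log2 = FALSE, norm = TRUE) {
  rows <- .region_bins(cm, region1)
  cols <- if (is.null(region2)) rows else .region_bins(cm, region2)
  sel <- (cm$pixels$bin1 %in% rows & cm$pixels$bin2 %in% cols) |
         (cm$pixels$bin1 %in% cols & cm$pixels$bin2 %in% rows)
  px <- cm$pixels[sel, ]
  v <- px$count
  if (norm || oe) v <- v * cm$bias[px$bin1] * cm$bias[px$bin2]
  M <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (oe) {
    cm <- .ensure_expected(cm)
    chrom1 <- cm$bins$chrom[px$bin1]
    chrom2 <- cm$bins$chrom[px$bin2]
    ev <- numeric(nrow(px))
    intra <- chrom1 == chrom2
    for (cc in unique(chrom1[intra])) {
      s <- intra & chrom1 == cc
      e <- .expected_for(cm, cc)
      ev[s] <- e[px$bin2[s] - px$bin1[s] + 1L]
    }
    ev[!intra] <- cm$expected$inter
    if (any(ev == 0 & v != 0)) stop("Expected value 0 at a distance with non-zero pixels")
    v <- ifelse(v == 0, 0, v / ev)
    # implicit zeros: O/E 0 (or -Inf after log2)
  }
  ri <- match(px$bin1, rows); ci <- match(px$bin2, cols)
  ok <- !is.na(ri) & !is.na(ci)
  M[cbind(ri[ok], ci[ok])] <- v[ok]
  ri2 <- match(px$bin2, rows); ci2 <- match(px$bin1, cols)
  ok2 <- !is.na(ri2) & !is.na(ci2)
  M[cbind(ri2[ok2], ci2[ok2])] <- v[ok2]
  if (log2) M <- base::log2(M)
  M[!cm$mask[rows], ] <- NA_real_
  M[, !cm$mask[cols]] <- NA_real_
  M
}

#' Virtual 4C profile from an anchor region
#'
#' Mean normalised (or O/E) contact value between the anchor bins and every
#' bin of the window region, as a tidy score track. Masked bins are excluded
#' from the anchor mean; masked window bins are `NA`.
#'
#' @param cm A `contact_matrix`.
#' @param anchor Anchor region (string or tibble row).
#' @param window Window region to profile across (default: the anchor's
#'   whole chromosome).
#' @param oe Use O/E values.
#' @return Tibble `chrom`, `start`, `end`, `score`.
#' @export
virtual_4c <- function(cm, anchor, window = NULL, oe = FALSE) {
  a <- .parse_region(cm, anchor)
  window <- window %||% a$chrom
  M <- fetch(cm, anchor, window, oe = oe)
  cols <- .region_bins(cm, window)
  score <- colMeans(M, na.rm = TRUE)
  score[colSums(!is.na(M)) == 0] <- NA_real_
  tibble(chrom = cm$bins$chrom[cols], start = cm$bins$start[cols],
         end = cm$bins$end[cols], score = as.numeric(score))
}

# ---- text I/O -------------------------------------------------------------

#' Write / read sparse triplet text ("bin1 bin2 value")
#' @param cm A `contact_matrix`.
#' @param path Output path.
#' @return `path` (write) or a pixel tibble (read), invisibly for write.
#' @export
write_triplets <- function(cm, path) {
  readr::write_tsv(cm$pixels, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_triplets
#' @param bins Bin tibble matching the triplet indices.
#' @export
read_triplets <- function(path, bins) {
  tab <- readr::read_tsv(path, col_names = c("bin1", "bin2", "count"),
                         show_col_types = FALSE, progress = FALSE)
  contact_matrix(tab, bins)
}

#' Write / read bedgraph2 text (chrom1 start1 end1 chrom2 start2 end2 value)
#' @inheritParams write_triplets
#' @export
write_bedgraph2 <- function(cm, path) {
  b1 <- cm$bins[cm$pixels$bin1, ]
  b2 <- cm$bins[cm$pixels$bin2, ]
  out <- tibble(chrom1 = b1$chrom, start1 = b1$start, end1 = b1$end,
                chrom2 = b2$chrom, start2 = b2$start, end2 = b2$end,
                value = cm$pixels$count)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph2
#' @export
read_bedgraph2 <- function(path, bins) {
  tab <- readr::read_tsv(path, col_names = c("chrom1", "start1", "end1",
                                             "chrom2", "start2", "end2", "value"),
                         show_col_types = FALSE, progress = FALSE)
  i1 <- locate_region(bins, tab$chrom1, tab$start1)
  i2 <- locate_region(bins, tab$chrom2, tab$start2)
  if (anyNA(c(i1, i2))) stop("bedgraph2 coordinates outside the bin set")
  contact_matrix(tibble(bin1 = bins$bin_id[i1], bin2 = bins$bin_id[i2],
                        count = tab$value), bins)
}

#' Save / load the native contact-matrix container
#'
#' The native container is a directory of deterministic tab-separated and
#' JSON files: `bins.tsv`, `pixels.tsv`, `bins_meta.tsv` (bias + mask),
#' `expected.json` and `metadata.json`. Round trips are value-exact.
#'
#' @param cm A `contact_matrix`.
#' @param dir Container directory (created if needed).
#' @return `dir` / the restored `contact_matrix`.
#' @export
write_cfm <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(cm$bins, file.path(dir, "bins.tsv"), progress = FALSE)
  readr::write_tsv(cm$pixels, file.path(dir, "pixels.tsv"), progress = FALSE)
  readr::write_tsv(tibble(bias = cm$bias, mask = cm$mask),
                   file.path(dir, "bins_meta.tsv"), progress = FALSE)
  jsonlite::write_json(list(chrom_lengths = as.list(cm$chrom_lengths),
                            bin_size = cm$bin_size, metadata = cm$metadata),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(cm$expected)) {
    jsonlite::write_json(cm$expected, file.path(dir, "expected.json"), digits = NA,
                         auto_unbox = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cfm
#' @export
read_cfm <- function(dir) {
  bins <- readr::read_tsv(file.path(dir, "bins.tsv"), show_col_types = FALSE, progress = FALSE)
  px <- readr::read_tsv(file.path(dir, "pixels.tsv"), show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"), simplifyVector = TRUE)
  bm <- readr::read_tsv(file.path(dir, "bins_meta.tsv"), show_col_types = FALSE, progress = FALSE)
  bins <- .set_chrom_lengths(as_tibble(bins), unlist(meta$chrom_lengths))
  attr(bins, "bin_size") <- meta$bin_size
  cm <- contact_matrix(px, bins, bias = bm$bias, mask = bm$mask,
                       metadata = as.list(meta$metadata))
  ef <- file.path(dir, "expected.json")
  if (file.exists(ef)) {
    e <- jsonlite::read_json(ef, simplifyVector = TRUE)
    e$inter <- as.numeric(e$inter)
    cm$expected <- e
  }
  cm
}
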