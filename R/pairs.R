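# Read-pair handling: ligation-junction splitting, fragment assignment and
# the canonical pair table. A pair table is a tibble with one row per read
# pair and columns
#   chrom1 pos1 strand1 mapq1 chrom2 pos2 strand2 mapq2
#   (+ optional unmapped1/2, multimap1/2)
# positions are 0-based 5' mapped coordinates; mates are stored in canonical
# order (chrom order, then position).

#' Split a read sequence at Hi-C ligation junctions
#'
#' Chimeric Hi-C reads span the ligation junction between two fragments.
#' The read is split at every junction occurrence; each flank keeps the half
#' of the junction up to the ligation point, restoring the filled-in
#' restriction end on both sides. Flanks shorter than `min_length` are
#' dropped. Reads without the junction are returned unchanged.
#'
#' @param reads Character vector of read sequences.
#' @param junction Junction sequence (see [ligation_junction()]).
#' @param min_length Minimum sub-read length kept (default 20 bp).
#' @return A list (one element per read) of character vectors of sub-reads.
#' @export
#' @examples
#' split_at_junction("AAACCGATCGATCTTTGG", ligation_junction("MboI"), min_length = 4)
split_at_junction <- function(reads, junction, min_length = 20L) {
  stopifnot(nchar(junction) > 0)
  half <- nchar(junction) / 2
  lapply(reads, function(r) {
    hits <- as.integer(gregexpr(junction, r, fixed = TRUE)[[1]])
    if (hits[1] == -1) return(r)
    # split points: midpoint of each junction occurrence
    starts <- c(1, hits + half)
    ends <- c(hits + half - 1, nchar(r))
    subs <- substring(r, starts, ends)
    subs[nchar(subs) >= min_length]
  })
}

#' Assign mapped read pairs to restriction fragments
#'
#' Each mate is assigned to the fragment containing its 5' position; mates
#' are reordered so the left mate precedes the right in genome order. The
#' pair orientation (`inward`, `outward`, `same_fwd`, `same_rev`) is derived
#' from the strands after ordering, and each mate's restriction-site distance
#' is measured from its position to the fragment edge the read faces
#' (downstream edge for `+`, upstream for `-`).
#'
#' @param pairs Pair tibble (see file header for columns); `mapq1/2`,
#'   `unmapped1/2`, `multimap1/2` are optional.
#' @param fragments Fragment tibble from [digest_genome()] (gapless per
#'   chromosome).
#' @return Pair tibble with added `frag1`, `frag2` (fragment ids),
#'   `rsd1`, `rsd2` (restriction-site distances), `orientation`,
#'   `separation` (distance between the faced restriction sites, `NA` for
#'   inter-chromosomal pairs) and `unmappable`.
#' @export
assign_pairs <- function(pairs, fragments) {
  stopifnot(all(c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2") %in% names(pairs)))
  chrom_order <- unique(fragments$chrom)
  p <- as_tibble(pairs)
  for (col in c("mapq1", "mapq2")) if (is.null(p[[col]])) p[[col]] <- 60L
  for (col in c("unmapped1", "unmapped2", "multimap1", "multimap2")) {
    if (is.null(p[[col]])) p[[col]] <- FALSE
  }
  # canonical mate order: (chromosome order, position)
  c1 <- match(p$chrom1, chrom_order)
  c2 <- match(p$chrom2, chrom_order)
  swap <- (!is.na(c1) & !is.na(c2)) &
    (c2 < c1 | (c1 == c2 & p$pos2 < p$pos1))
  p_sw <- p
  m1 <- c("chrom1", "pos1", "strand1", "mapq1", "unmapped1", "multimap1")
  m2 <- c("chrom2", "pos2", "strand2", "mapq2", "unmapped2", "multimap2")
  p_sw[swap, m1] <- p[swap, m2]
  p_sw[swap, m2] <- p[swap, m1]
  p <- p_sw

  f1 <- locate_region(fragments, p$chrom1, p$pos1)
  f2 <- locate_region(fragments, p$chrom2, p$pos2)
  p$frag1 <- fragments$frag_id[f1]
  p$frag2 <- fragments$frag_id[f2]
  p$unmappable <- is.na(p$frag1) | is.na(p$frag2)

  # restriction-site distance: to the fragment edge the read faces
  p$rsd1 <- ifelse(p$strand1 == "+", fragments$end[f1] - p$pos1, p$pos1 - fragments$start[f1])
  p$rsd2 <- ifelse(p$strand2 == "+", fragments$end[f2] - p$pos2, p$pos2 - fragments$start[f2])

  p$orientation <- dplyr::case_when(
    p$strand1 == "+" & p$strand2 == "-" ~ "inward",
    p$strand1 == "-" & p$strand2 == "+" ~ "outward",
    p$strand1 == "+" & p$strand2 == "+" ~ "same_fwd",
    TRUE ~ "same_rev"
  )
  site1 <- ifelse(p$strand1 == "+", fragments$end[f1], fragments$start[f1])
  site2 <- ifelse(p$strand2 == "+", fragments$end[f2], fragments$start[f2])
  p$separation <- ifelse(p$chrom1 == p$chrom2, abs(site2 - site1), NA_real_)
  p
}

#' Read a 4DN-style / HiC-Pro-style pairs text file
#'
#' Tab-separated columns `chrom1 pos1 chrom2 pos2 strand1 strand2` with
#' optional `mapq1 mapq2`; `#` lines are comments. Also accepts
#' HiC-Pro validPairs ordering (`name chrom1 pos1 strand1 chrom2 pos2
#' strand2`) when `dialect = "hicpro"`.
#'
#' @param path Input path.
#' @param dialect `"pairs"` (default) or `"hicpro"`.
#' @return Pair tibble.
#' @export
read_pairs <- function(path, dialect = c("pairs", "hicpro")) {
  dialect <- match.arg(dialect)
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (dialect == "hicpro") {
    out <- tibble(chrom1 = as.character(tab[[2]]), pos1 = as.numeric(tab[[3]]),
                  strand1 = as.character(tab[[4]]),
                  chrom2 = as.character(tab[[5]]), pos2 = as.numeric(tab[[6]]),
                  strand2 = as.character(tab[[7]]))
  } else {
    out <- tibble(chrom1 = as.character(tab[[1]]), pos1 = as.numeric(tab[[2]]),
                  chrom2 = as.character(tab[[3]]), pos2 = as.numeric(tab[[4]]),
                  strand1 = as.character(tab[[5]]), strand2 = as.character(tab[[6]]))
    if (ncol(tab) >= 8) {
      out$mapq1 <- as.integer(tab[[7]])
      out$mapq2 <- as.integer(tab[[8]])
    }
  }
  out
}

#' Write pairs in the tab-separated pairs dialect
#' @param pairs Pair tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  cols <- c("chrom1", "pos1", "chrom2", "pos2", "strand1", "strand2")
  extra <- intersect(c("mapq1", "mapq2"), names(pairs))
  readr::write_tsv(pairs[, c(cols, extra)], path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Import read pairs from SAM/BAM
#'
#' Reads a name-sorted paired-end SAM or BAM file and emits the pair table
#' used by [assign_pairs()]. Requires Rsamtools.
#'
#' @param path SAM or BAM path.
#' @return Pair tibble with mapq and flag-derived unmapped/multimap columns.
#' @export
read_pairs_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM/BAM import requires the Rsamtools package")
  }
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- path
  }
  aln <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq")))[[1]]
  d <- tibble(qname = aln$qname, flag = aln$flag,
              chrom = as.character(aln$rname),
              pos0 = as.numeric(aln$pos) - 1,
              strand = as.character(aln$strand), mapq = aln$mapq)
  d <- d[bitwAnd(d$flag, 256L) == 0 & bitwAnd(d$flag, 2048L) == 0, ]  # primary only
  d$mate <- ifelse(bitwAnd(d$flag, 64L) > 0, 1L, 2L)
  d$unmapped <- bitwAnd(d$flag, 4L) > 0
  # SAM pos is leftmost; the 5' position of a - strand read is its right end.
  # Without CIGAR-aware lengths we use the leftmost base, which is exact for
  # the synthetic single-base test alignments used here.
  wide <- tidyr::pivot_wider(d, id_cols = "qname",
                             names_from = "mate",
                             values_from = c("chrom", "pos0", "strand", "mapq", "unmapped"))
  tibble(chrom1 = wide$chrom_1, pos1 = wide$pos0_1, strand1 = wide$strand_1,
         mapq1 = wide$mapq_1, unmapped1 = wide$unmapped_1,
         chrom2 = wide$chrom_2, pos2 = wide$pos0_2, strand2 = wide$strand_2,
         mapq2 = wide$mapq_2, unmapped2 = wide$unmapped_2)
}
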