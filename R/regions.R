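# Region sets are tibbles with columns chrom, start, end (0-based half-open)
# plus optional strand/name/score, carrying a "chrom_lengths" attribute (a
# named numeric in the canonical chromosome order). bin_id / frag_id columns
# are dense 1-based indices in that order.

.set_chrom_lengths <- function(x, lengths) {
  attr(x, "chrom_lengths") <- lengths
  x
}

#' Chromosome lengths attached to a region set
#' @param x A region tibble produced by [make_bins()], [digest_genome()] or
#'   [read_regions()].
#' @return Named numeric vector of chromosome lengths in canonical order, or
#'   `NULL` when unknown.
#' @export
chrom_lengths <- function(x) attr(x, "chrom_lengths")

.order_regions <- function(x, chrom_order = NULL) {
  if (is.null(chrom_order)) chrom_order <- unique(x$chrom)
  x$chrom <- factor(x$chrom, levels = chrom_order)
  x <- arrange(x, .data$chrom, .data$start)
  x$chrom <- as.character(x$chrom)
  x
}

#' Partition a genome into fixed-size bins
#'
#' Each chromosome is tiled with `[0, b), [b, 2b), ...`; the last bin is
#' truncated at the chromosome end. Bins get a dense 1-based `bin_id` in
#' chromosome order.
#'
#' @param lengths Named numeric vector of chromosome lengths (bp), in the
#'   desired chromosome order.
#' @param bin_size Bin width in bp, `> 0`.
#' @return Tibble with `chrom`, `start`, `end`, `bin_id` and a
#'   `chrom_lengths` attribute.
#' @export
#' @examples
#' make_bins(c(chr1 = 25), bin_size = 10)
make_bins <- function(lengths, bin_size) {
  stopifnot(is.numeric(lengths), !is.null(names(lengths)), bin_size > 0)
  bins <- purrr::imap_dfr(as.list(lengths), function(len, chrom) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble(chrom = chrom, start = starts, end = pmin(starts + bin_size, len))
  })
  bins$bin_id <- seq_len(nrow(bins))
  out <- .set_chrom_lengths(bins, lengths)
  attr(out, "bin_size") <- bin_size
  out
}

#' Digest genome sequences with one or more restriction enzymes
#'
#' Scans each chromosome for occurrences of the recognition site(s)
#' (IUPAC ambiguity codes match degenerately) and cuts at
#' `match_start + cut_offset`. Fragments are the intervals between successive
#' cut positions; they tile each chromosome gaplessly and zero-length
#' fragments are dropped. With several enzymes the union of cut positions is
#' used (mixed digests).
#'
#' @param genome A named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param enzyme Enzyme name(s) (see [restriction_enzyme()]) or an enzyme
#'   tibble from [custom_enzyme()].
#' @return Fragment tibble with `chrom`, `start`, `end`, `frag_id` and a
#'   `chrom_lengths` attribute. Chromosome order is the FASTA order.
#' @export
#' @examples
#' digest_genome(c(chrA = "GAAGCTTC"), "HindIII")
digest_genome <- function(genome, enzyme) {
  genome <- .as_dnastringset(genome)
  if (any(Biostrings::width(genome) == 0)) {
    stop("Empty sequence for chromosome(s): ",
         paste(names(genome)[Biostrings::width(genome) == 0], collapse = ", "))
  }
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  lens <- setNames(as.numeric(Biostrings::width(genome)), names(genome))
  frags <- purrr::imap_dfr(setNames(seq_along(genome), names(genome)), function(k, chrom) {
    len <- lens[[chrom]]
    cuts <- unlist(lapply(seq_len(nrow(enzyme)), function(e) {
      m <- Biostrings::matchPattern(enzyme$site[e], genome[[k]], fixed = FALSE)
      if (length(m) == 0) return(integer(0))
      (Biostrings::start(m) - 1L) + enzyme$cut_offset[e]
    }))
    bounds <- sort(unique(c(0, cuts[cuts > 0 & cuts < len], len)))
    tibble(chrom = chrom, start = bounds[-length(bounds)], end = bounds[-1])
  })
  frags <- frags[frags$end > frags$start, ]
  frags$frag_id <- seq_len(nrow(frags))
  .set_chrom_lengths(frags, lens)
}

.as_dnastringset <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a FASTA path, a DNAStringSet, or a named character vector")
}

#' Locate the fragment or bin containing each genomic position
#'
#' @param regions A gapless fragment/bin tibble (per chromosome).
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @return Integer vector of row indices into `regions` (`NA` where the
#'   chromosome is absent or the position out of range).
#' @export
locate_region <- function(regions, chrom, pos) {
  idx <- rep(NA_integer_, length(chrom))
  for (cc in unique(chrom)) {
    rows <- which(regions$chrom == cc)
    if (length(rows) == 0) next
    sel <- which(chrom == cc)
    j <- findInterval(pos[sel], regions$start[rows])
    ok <- j >= 1 & pos[sel] < regions$end[rows[pmax(j, 1)]]
    idx[sel[ok]] <- rows[j[ok]]
  }
  idx
}

#' Read genomic regions from BED, GFF or tabular score files
#'
#' BED is read natively (already 0-based half-open); GFF coordinates are
#' converted from 1-based inclusive. bedGraph-style tabular score files
#' (`chrom start end score`) are read as BED with a `score` column.
#'
#' @param path File path.
#' @param format One of `"bed"`, `"gff"`, `"bedgraph"`; guessed from the file
#'   extension by default.
#' @return Region tibble with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `strand` present in the file.
#' @export
read_regions <- function(path, format = c("auto", "bed", "gff", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      "bed" = "bed", "gff" = "gff", "gff3" = "gff", "gtf" = "gff",
      "bedgraph" = "bedgraph", "bdg" = "bedgraph", "bed")
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    warning("Empty region file: ", path)
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  if (format == "gff") {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      stop("GFF import requires the rtracklayer package")
    }
    gr <- rtracklayer::import(path)
    out <- tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1,   # to 0-based half-open
      end = as.numeric(GenomicRanges::end(gr)),
      strand = as.character(GenomicRanges::strand(gr))
    )
    if (!is.null(gr$score)) out$score <- as.numeric(gr$score)
    return(out)
  }
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 3) stop("Expected at least 3 columns in ", path)
  out <- tibble(chrom = as.character(tab[[1]]),
                start = as.numeric(tab[[2]]), end = as.numeric(tab[[3]]))
  bad <- which(!(out$start >= 0 & out$end > out$start))
  if (length(bad)) stop("Malformed region at line ", bad[1], " of ", path)
  if (format == "bedgraph") {
    if (ncol(tab) >= 4) out$score <- as.numeric(tab[[4]])
    return(out)
  }
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  if (ncol(tab) >= 5) out$score <- suppressWarnings(as.numeric(tab[[5]]))
  if (ncol(tab) >= 6) out$strand <- as.character(tab[[6]])
  out
}

#' Write regions to BED
#'
#' Canonical 6-column BED output (or fewer columns when name/score/strand are
#' absent). Round trips with [read_regions()] byte-identically for canonical
#' 6-column input.
#'
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- list(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE))
  if (!is.null(regions[["name"]]) || !is.null(regions[["score"]]) || !is.null(regions[["strand"]])) {
    cols <- c(cols, list(regions[["name"]] %||% rep(".", nrow(regions))))
  }
  if (!is.null(regions[["score"]]) || !is.null(regions[["strand"]])) {
    sc <- regions[["score"]] %||% rep(0, nrow(regions))
    cols <- c(cols, list(format(sc, scientific = FALSE, trim = TRUE)))
  }
  if (!is.null(regions[["strand"]])) cols <- c(cols, list(regions[["strand"]]))
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-bin score track to bedGraph
#' @param track Tibble with `chrom`, `start`, `end` and one score column.
#' @param path Output path.
#' @param column Score column name (default: the 4th column).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, column = NULL) {
  column <- column %||% setdiff(names(track), c("chrom", "start", "end", "bin_id"))[1]
  keep <- !is.na(track[[column]])
  readr::write_tsv(track[keep, c("chrom", "start", "end", column)], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Parse genomic size strings such as "25kb" or "1mb"
#' @param x Character or numeric vector.
#' @return Numeric bp values.
#' @export
parse_bp <- function(x) {
  if (is.numeric(x)) return(x)
  mult <- dplyr::case_when(
    grepl("mb$", tolower(x)) ~ 1e6,
    grepl("kb$", tolower(x)) ~ 1e3,
    TRUE ~ 1
  )
  as.numeric(gsub("(?i)[km]?b$", "", x, perl = TRUE)) * mult
}
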