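# One-command pipeline: pairs -> assign -> filter -> bin -> coverage filter
# -> balance -> expected values, per requested resolution.

#' Run the full matrix-generation pipeline on a pair input
#'
#' Accepts a pair tibble, a pairs text file, or a SAM/BAM file (the format
#' is detected from the extension); assigns pairs to fragments, applies the
#' artefact filter suite, bins at each requested resolution, masks
#' low-coverage bins, balances and stores expected values.
#'
#' @param input Pair tibble or path (`.tsv`/`.pairs` text, `.sam`/`.bam`).
#' @param fragments Fragment tibble (from [digest_genome()] or a custom
#'   restriction map via [read_regions()]).
#' @param resolutions Bin sizes in bp (accepts `"25kb"` style strings).
#' @param filter_config From [pair_filter_config()].
#' @param norm `"kr"` or `"ice"`.
#' @param coverage_fraction Coverage cutoff as fraction of the median
#'   marginal (default 0.25).
#' @return List: `matrices` (named by resolution), `stats` (filter counts),
#'   `diagnostics` (from [pair_diagnostics()]), `pairs` (the valid pairs).
#' @export
hic_auto <- function(input, fragments, resolutions,
                     filter_config = pair_filter_config(),
                     norm = c("kr", "ice"), coverage_fraction = 0.25) {
  norm <- match.arg(norm)
  if (is.character(input)) {
    ext <- tolower(tools::file_ext(input))
    input <- switch(ext,
      "sam" = , "bam" = read_pairs_sam(input),
      "tsv" = , "pairs" = , "txt" = read_pairs(input),
      "fastq" = , "fq" = stop("FASTQ input requires external alignment first; ",
                              "supply aligned pairs (SAM/BAM or pairs text)"),
      stop("Cannot detect input format of '", input,
           "' (tried: pairs text, SAM/BAM)"))
  }
  resolutions <- parse_bp(resolutions)
  assigned <- assign_pairs(input, fragments)
  flt <- filter_pairs(assigned, filter_config)
  diags <- pair_diagnostics(assigned)
  lens <- chrom_lengths(fragments)
  mats <- lapply(resolutions, function(res) {
    bins <- make_bins(lens, res)
    cm <- bin_pairs(flt$pairs, bins, fragments)
    cm <- matrix_filters(cm, coverage_fraction = coverage_fraction)
    cm <- balance_matrix(cm, method = norm)
    expected_values(cm)
  })
  names(mats) <- format(resolutions, scientific = FALSE, trim = TRUE)
  list(matrices = mats, stats = flt$stats, diagnostics = diags,
       pairs = flt$pairs)
}
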