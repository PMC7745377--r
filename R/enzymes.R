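# Built-in restriction enzymes. cut_offset is the 0-based position of the cut
# within the recognition site on the + strand ("A^AGCTT" -> offset 1).
.enzyme_table <- tibble::tribble(
  ~name,      ~site,     ~cut_offset,
  "HindIII",  "AAGCTT",  1L,
  "MboI",     "GATC",    0L,
  "DpnII",    "GATC",    0L,
  "Sau3AI",   "GATC",    0L,
  "NlaIII",   "CATG",    4L,
  "EcoRI",    "GAATTC",  1L,
  "BglII",    "AGATCT",  1L,
  "NcoI",     "CCATGG",  1L,
  "ApoI",     "RAATTY",  1L,
  "AluI",     "AGCT",    2L,
  "HaeIII",   "GGCC",    2L,
  "Arima",    NA,        NA  # mixed digest: MboI + HinfI-like handled below
)

#' Look up one or more restriction enzymes
#'
#' Returns the recognition site and cut offset for each named enzyme from the
#' built-in table. `"Arima"` expands to the MboI + NlaIII two-enzyme mix used
#' by Arima-style kits; any comma-separated list of names is accepted, and a
#' multi-enzyme digest takes the union of all cut positions.
#'
#' @param name Character vector of enzyme names (case-insensitive), or a
#'   single comma-separated string such as `"MboI,NlaIII"`.
#' @return A tibble with columns `name`, `site` (IUPAC string) and
#'   `cut_offset` (0-based position of the cut within the site).
#' @export
#' @examples
#' restriction_enzyme("HindIII")
#' restriction_enzyme("MboI,NlaIII")
restriction_enzyme <- function(name) {
  stopifnot(is.character(name), length(name) >= 1)
  name <- unlist(strsplit(name, ","))
  name <- trimws(name)
  out <- purrr::map_dfr(name, function(nm) {
    if (tolower(nm) == "arima") {
      return(dplyr::filter(.enzyme_table, .data$name %in% c("MboI", "NlaIII")))
    }
    hit <- dplyr::filter(.enzyme_table, tolower(.data$name) == tolower(nm))
    if (nrow(hit) == 0) {
      stop("Unknown enzyme '", nm, "'. Supported enzymes: ",
           paste(.enzyme_table$name, collapse = ", "),
           ". Alternatively supply a custom fragment map.", call. = FALSE)
    }
    hit
  })
  dplyr::distinct(out, .data$site, .data$cut_offset, .keep_all = TRUE) |>
    dplyr::select("name", "site", "cut_offset")
}

#' Construct a custom restriction enzyme
#'
#' @param name Display name.
#' @param site IUPAC recognition site.
#' @param cut_offset 0-based cut position within the site, `0 <= offset <= nchar(site)`.
#' @return One-row tibble compatible with [restriction_enzyme()].
#' @export
custom_enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  stopifnot(nchar(site) > 0, cut_offset >= 0, cut_offset <= nchar(site))
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site)) {
    stop("Recognition site must be an IUPAC DNA string, got '", site, "'")
  }
  tibble(name = name, site = site, cut_offset = as.integer(cut_offset))
}

.is_palindromic <- function(site) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  identical(site, rc)
}

#' Ligation junction sequence of a restriction enzyme
#'
#' Hi-C ligation junctions arise when two restriction ends are cut, their 5'
#' overhangs filled in, and the blunted ends ligated. For a palindromic site
#' cut at offset `c` (5' overhang or blunt), the junction is
#' `site[1..c] + site[c+1..L-c] + site[c+1..L-c] + site[L-c+1..L]`; blunt
#' cutters return the site itself.
#'
#' @param enzyme One-row enzyme tibble from [restriction_enzyme()] or
#'   [custom_enzyme()], or an enzyme name.
#' @return Junction DNA string.
#' @export
#' @examples
#' ligation_junction("HindIII")  # "AAGCTAGCTT"
#' ligation_junction("MboI")     # "GATCGATC"
ligation_junction <- function(enzyme) {
  if (is.character(enzyme)) enzyme <- restriction_enzyme(enzyme)
  stopifnot(nrow(enzyme) >= 1)
  vapply(seq_len(nrow(enzyme)), function(k) {
    site <- enzyme$site[k]
    cut <- enzyme$cut_offset[k]
    L <- nchar(site)
    if (!.is_palindromic(site)) {
      stop("Ligation junction is ambiguous for non-palindromic site '", site, "'")
    }
    if (cut > L / 2) {
      stop("3' overhang cutters (cut offset ", cut, " in ", L,
           " bp site) are not supported for junction derivation")
    }
    if (cut == L / 2) return(site)  # blunt
    mid <- substr(site, cut + 1, L - cut)
    paste0(substr(site, 1, cut), mid, mid, substr(site, L - cut + 1, L))
  }, character(1))
}
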