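#' Create a genomic region
#'
#' Regions are one-row tibbles with a fixed, 0-based half-open coordinate
#' convention: a region covers bases `start, start + 1, ..., end - 1`, so its
#' length is `end - start`. All coordinates inside the package use this
#' convention.
#'
#' @param chrom Chromosome / contig name.
#' @param start,end Region boundaries, `start < end`, half-open.
#' @param name Optional region name.
#' @return A one-row tibble with columns `chrom`, `start`, `end`, `name`.
#' @examples
#' region("chr3", 131019746, 131020624, "Leaf")
#' @export
region <- function(chrom, start, end, name = NA_character_) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nchar(chrom) > 0L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end) {
    stop("invalid region: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = as.character(name))
}

#' Parse a region string
#'
#' Accepts UCSC-style strings such as `"chr3:131,019,746-131,020,624"`.
#' Thousands separators (commas, apostrophes, primes) are stripped and any
#' dash variant (hyphen, en-dash, em-dash, minus) separates start from end.
#'
#' Printed coordinates are taken as-is under the half-open convention, so the
#' parsed length is `end - start`. This matches how published region lengths
#' in this locus are computed (e.g. the 878 bp Leaf element).
#'
#' @param x A single region string.
#' @param name Optional region name.
#' @return A one-row region tibble (see [region()]).
#' @examples
#' parse_region("chr3:131,019,746-131,020,624", name = "Leaf")
#' @export
parse_region <- function(x, name = NA_character_) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("[ ,'′´]", "", x)
  s <- gsub("[–—−]", "-", s)
  m <- regmatches(s, regexec("^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) {
    stop("cannot parse region string: '", x, "'")
  }
  region(m[2], as.numeric(m[3]), as.numeric(m[4]), name = name)
}

#' Region length and center
#'
#' `region_length()` is `end - start` (half-open convention);
#' `region_center()` is the midpoint `(start + end) / 2`.
#'
#' @param r A region tibble (or any data frame with `start`/`end`).
#' @return A numeric vector, one value per row of `r`.
#' @export
region_length <- function(r) {
  r$end - r$start
}

#' @rdname region_length
#' @export
region_center <- function(r) {
  (r$start + r$end) / 2
}

format_region <- function(r) {
  sprintf("%s:%d-%d", r$chrom, as.integer(r$start), as.integer(r$end))
}

#' Reference regions of the Lef1/Leaf locus (mm10)
#'
#' The named mm10 intervals used throughout the Leaf--Lef1 contact analysis:
#' the viewpoint exclusion windows around the Lef1-promoter and Leaf baits,
#' the two analyzed target regions, the conserved 878 bp Leaf element, and
#' its 521 bp sub-region deleted in several primates.
#'
#' @return A tibble with columns `name`, `role`, `chrom`, `start`, `end`.
#' @examples
#' study_regions()
#' @export
study_regions <- function() {
  tibble::tribble(
    ~name,                     ~role,                  ~chrom, ~start,     ~end,
    "lef1_promoter_exclusion", "viewpoint_exclusion",  "chr3", 131104979, 131112546,
    "leaf_exclusion",          "viewpoint_exclusion",  "chr3", 131016310, 131022769,
    "leaf_region",             "analysis_region",      "chr3", 131008663, 131026430,
    "lef1_region",             "analysis_region",      "chr3", 131106987, 131227057,
    "leaf_element",            "conserved_element",    "chr3", 131019746, 131020624,
    "leaf_primate_deletion",   "deleted_subregion",    "chr3", 131020103, 131020624
  )
}

study_region <- function(name) {
  tab <- study_regions()
  row <- tab[tab$name == name, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown study region: ", name)
  region(row$chrom, row$start, row$end, name = row$name)
}
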