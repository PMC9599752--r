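#' Define a restriction enzyme
#'
#' An enzyme is its recognition motif plus the offset (in bases from the
#' motif start) at which the cut falls. NlaIII cuts after its site
#' (`CATG^`, offset 4); DpnII cuts before its site (`^GATC`, offset 0).
#' Both motifs are their own reverse complements, so a single-strand scan
#' finds all sites; user-supplied enzymes with non-palindromic motifs are
#' rejected because the scan would miss minus-strand sites.
#'
#' @param name Enzyme name.
#' @param motif Recognition motif, uppercase DNA over A/C/G/T.
#' @param cut_offset Integer offset of the cut from the motif start,
#'   `0 <= cut_offset <= nchar(motif)`.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("NlaIII", "CATG", 4)
#' @export
restriction_enzyme <- function(name, motif, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L)
  motif <- toupper(as.character(motif))
  if (!grepl("^[ACGT]+$", motif)) {
    stop("enzyme motif must be a non-empty string over A/C/G/T, got '",
         motif, "'")
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(motif)) {
    stop("cut_offset must lie in [0, ", nchar(motif), "] for motif ", motif)
  }
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]),
                                     collapse = ""))
  if (!identical(rc, motif)) {
    stop("motif ", motif, " is not its own reverse complement; ",
         "single-strand scanning would miss minus-strand sites")
  }
  structure(list(name = name, motif = motif, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s %s^%s\n", x$name,
              substr(x$motif, 1, x$cut_offset),
              substr(x$motif, x$cut_offset + 1, nchar(x$motif))))
  invisible(x)
}

#' Built-in 4C cutters
#'
#' The primary (NlaIII, `CATG^`) and secondary (DpnII, `^GATC`) cutters used
#' for the double digest.
#'
#' @return A `restriction_enzyme`.
#' @export
enzyme_nlaiii <- function() restriction_enzyme("NlaIII", "CATG", 4L)

#' @rdname enzyme_nlaiii
#' @export
enzyme_dpnii <- function() restriction_enzyme("DpnII", "GATC", 0L)

#' Parse an enzyme specification string
#'
#' Accepts `"Name:MOTIF:offset"` (e.g. `"NlaIII:CATG:4"`) as used in
#' pipeline configuration files.
#'
#' @param x A single specification string.
#' @return A `restriction_enzyme`.
#' @export
parse_enzyme <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    stop("enzyme spec must be 'Name:MOTIF:offset', got '", x, "'")
  }
  restriction_enzyme(parts[1], parts[2], as.integer(parts[3]))
}

#' Locate enzyme cut sites in a sequence
#'
#' Scans a DNA sequence for exact occurrences of the enzyme motif
#' (overlapping occurrences included) and returns the 0-based cut
#' coordinates `motif start + cut_offset`. The sequence is uppercased first;
#' ambiguity codes such as `N` never match.
#'
#' @param sequence A single DNA string or a [Biostrings::DNAString].
#' @param enzyme A `restriction_enzyme`.
#' @return A sorted numeric vector of 0-based cut coordinates (empty for an
#'   empty sequence or no occurrence).
#' @examples
#' find_motif_sites("AACATGGTTGATCAACATGA", enzyme_nlaiii())
#' @export
find_motif_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  if (is.character(sequence)) {
    stopifnot(length(sequence) == 1L)
    if (nchar(sequence) == 0L) return(numeric(0))
    sequence <- Biostrings::DNAString(toupper(sequence))
  }
  if (length(sequence) < nchar(enzyme$motif)) return(numeric(0))
  hits <- Biostrings::matchPattern(enzyme$motif, sequence, fixed = TRUE)
  starts0 <- Biostrings::start(hits) - 1
  sort(starts0 + enzyme$cut_offset)
}
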