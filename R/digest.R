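#' In-silico double digestion of a genome
#'
#' Cuts every contig at the primary enzyme's sites and returns the resulting
#' restriction fragment map. Fragments are the intervals between consecutive
#' primary cuts (plus the contig ends), so they tile each contig exactly:
#' the first fragment starts at 0, the last ends at the contig length, and
#' the fragment count equals the number of primary sites + 1. A fragment end
#' is flagged *blind* when no secondary-enzyme cut falls strictly inside the
#' fragment; blind ends capture poorly in 4C and are conventionally dropped
#' from scoring (see [assign_reads()]).
#'
#' @param genome A named character vector of DNA strings, a
#'   [Biostrings::DNAStringSet], or the path of a FASTA file.
#' @param primary,secondary `restriction_enzyme` objects; defaults are the
#'   NlaIII/DpnII pair.
#' @return A `fragment_map`: a tibble with columns `chrom`, `start`, `end`,
#'   `index` (ordinal within chromosome), `blind_left`, `blind_right`, and
#'   attributes `enzymes` and `contig_lengths`.
#' @examples
#' digest_genome(c(toy = "AACATGGTTGATCAACATGA"))
#' @export
digest_genome <- function(genome, primary = enzyme_nlaiii(),
                          secondary = enzyme_dpnii()) {
  stopifnot(inherits(primary, "restriction_enzyme"),
            inherits(secondary, "restriction_enzyme"))
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      !grepl("^[ACGTNacgtn]+$", genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome),
                              sub("\\s.*$", "", names(genome)))
  }
  stopifnot(is.character(genome), length(genome) >= 1L)
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome contigs must be named")
  }

  per_chrom <- purrr::imap(genome, function(seq, chrom) {
    seq <- toupper(seq)
    len <- nchar(seq)
    cuts1 <- find_motif_sites(seq, primary)
    cuts1 <- cuts1[cuts1 > 0 & cuts1 < len]
    cuts2 <- find_motif_sites(seq, secondary)
    bounds <- unique(c(0, cuts1, len))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    # a fragment end is blind when no secondary cut lies strictly inside
    n_inside <- findInterval(ends - 0.5, cuts2) -
      findInterval(starts + 0.5, cuts2)
    tibble::tibble(chrom = chrom, start = starts, end = ends,
                   index = seq_along(starts),
                   blind_left = n_inside == 0L,
                   blind_right = n_inside == 0L)
  })
  map <- dplyr::bind_rows(per_chrom)
  new_fragment_map(map,
                   enzymes = list(primary = primary, secondary = secondary),
                   contig_lengths = vapply(genome, nchar, numeric(1)))
}

new_fragment_map <- function(df, enzymes = NULL, contig_lengths = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "enzymes") <- enzymes
  attr(out, "contig_lengths") <- contig_lengths
  class(out) <- unique(c("fragment_map", class(out)))
  out
}

#' Write / read a fragment map as BED
#'
#' One BED6 record per fragment; the name column encodes the fragment index
#' and its blind-end flags (`<index>:<blind_left><blind_right>`), so the map
#' round-trips losslessly. Comment headers record the enzyme pair. Writing is
#' deterministic: identical maps give byte-identical files.
#'
#' @param map A `fragment_map`.
#' @param path Destination / source file path.
#' @return `write_fragment_map()` returns `path` invisibly;
#'   `read_fragment_map()` returns a `fragment_map`.
#' @export
write_fragment_map <- function(map, path) {
  stopifnot(inherits(map, "fragment_map"))
  enz <- attr(map, "enzymes")
  hdr <- character(0)
  if (!is.null(enz)) {
    hdr <- c(
      sprintf("#primary=%s:%s:%d", enz$primary$name, enz$primary$motif,
              enz$primary$cut_offset),
      sprintf("#secondary=%s:%s:%d", enz$secondary$name, enz$secondary$motif,
              enz$secondary$cut_offset))
  }
  rows <- sprintf("%s\t%d\t%d\t%d:%d%d\t0\t.",
                  map$chrom, as.integer(map$start), as.integer(map$end),
                  map$index, as.integer(map$blind_left),
                  as.integer(map$blind_right))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  enzymes <- NULL
  p <- sub("^#primary=", "", hdr[startsWith(hdr, "#primary=")])
  s <- sub("^#secondary=", "", hdr[startsWith(hdr, "#secondary=")])
  if (length(p) == 1L && length(s) == 1L) {
    enzymes <- list(primary = parse_enzyme(p), secondary = parse_enzyme(s))
  }
  if (length(body) == 0L) {
    empty <- tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), index = integer(),
                            blind_left = logical(), blind_right = logical())
    return(new_fragment_map(empty, enzymes = enzymes,
                            contig_lengths = numeric(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nm <- vapply(f, `[`, "", 4)
  nm_parts <- regmatches(nm, regexec("^([0-9]+):([01])([01])$", nm))
  if (any(lengths(nm_parts) != 4L)) {
    stop("malformed fragment name column in ", path)
  }
  df <- tibble::tibble(
    chrom = vapply(f, `[`, "", 1),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3)),
    index = as.integer(vapply(nm_parts, `[`, "", 2)),
    blind_left = vapply(nm_parts, `[`, "", 3) == "1",
    blind_right = vapply(nm_parts, `[`, "", 4) == "1")
  lens <- vapply(split(df$end, df$chrom), max, numeric(1))
  new_fragment_map(df, enzymes = enzymes, contig_lengths = lens)
}
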