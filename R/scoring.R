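new_score_track <- function(df, stage, bait = NULL, excluded = NULL,
                            unassigned = 0, n_removed = 0, norm_mean = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "stage") <- stage
  attr(out, "bait") <- bait
  attr(out, "excluded") <- excluded
  attr(out, "unassigned") <- unassigned
  attr(out, "n_removed") <- n_removed
  attr(out, "norm_mean") <- norm_mean
  class(out) <- unique(c("score_track", class(out)))
  out
}

track_meta <- function(track) {
  list(stage = attr(track, "stage"), bait = attr(track, "bait"),
       excluded = attr(track, "excluded"),
       unassigned = attr(track, "unassigned"),
       n_removed = attr(track, "n_removed"),
       norm_mean = attr(track, "norm_mean"))
}

#' Processing stage of a score track
#'
#' Tracks move through the fixed stage order
#' `raw -> normalized -> smoothed` (visualization branch) and
#' `raw -> normalized -> profile_corrected` (testing branch); each
#' processing function asserts the stage of its input.
#'
#' @param track A `score_track`.
#' @return The stage label, one of `"raw"`, `"normalized"`, `"smoothed"`,
#'   `"profile_corrected"`.
#' @export
track_stage <- function(track) {
  attr(track, "stage")
}

track_midpoint <- function(track) {
  (track$start + track$end) / 2
}

assert_stage <- function(track, allowed, fun) {
  st <- track_stage(track)
  if (is.null(st) || !st %in% allowed) {
    stop(fun, "() expects a track at stage ",
         paste(allowed, collapse = "/"), ", got '", st %||% "NULL", "'")
  }
  invisible(st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert aligned reads into per-fragment contact scores
#'
#' 4C reads start at restriction sites, so a read is anchored to the
#' fragment boundary nearest its 5' end: plus-strand reads are matched
#' against fragment starts and minus-strand reads against fragment ends
#' (the read extends into the fragment it is assigned to). A read whose 5'
#' end lies farther than `end_tolerance` bases from every matching boundary,
#' or on a chromosome absent from the map, is tallied as unassigned rather
#' than erroring. The fragment score is the raw count summed over both ends.
#'
#' Fragments blind on both ends are dropped unless `keep_blind = TRUE`;
#' reads falling on dropped fragments move to the unassigned tally so that
#' `sum(score) + unassigned` always equals the number of input reads.
#'
#' @param reads Tibble with columns `chrom`, `start`, `end`, `strand`
#'   (`+`/`-`; missing strand is treated as `+`). The 5' end is `start` on
#'   the plus strand and `end` on the minus strand.
#' @param map A `fragment_map` from [digest_genome()].
#' @param end_tolerance Maximum distance (bases) between a read 5' end and a
#'   fragment boundary; default 5 absorbs soft-clipped bases.
#' @param keep_blind Keep fragments blind on both ends? Default `FALSE`.
#' @return A raw `score_track`: the retained fragments with a `score`
#'   column, plus an `unassigned` attribute.
#' @export
assign_reads <- function(reads, map, end_tolerance = 5, keep_blind = FALSE) {
  stopifnot(inherits(map, "fragment_map"),
            all(c("chrom", "start") %in% names(reads)))
  if (!"strand" %in% names(reads)) reads$strand <- "+"
  reads$strand[is.na(reads$strand) | !reads$strand %in% c("+", "-")] <- "+"
  if (!"end" %in% names(reads)) reads$end <- reads$start + 1

  frag <- tibble::as_tibble(map)
  frag$score <- 0
  n_reads <- nrow(reads)
  unassigned <- 0

  for (chr in unique(reads$chrom)) {
    rd <- reads[reads$chrom == chr, , drop = FALSE]
    fi <- which(frag$chrom == chr)
    if (length(fi) == 0L) {
      unassigned <- unassigned + nrow(rd)
      next
    }
    p5 <- ifelse(rd$strand == "+", rd$start, rd$end)
    anchors <- ifelse(rd$strand == "+", "start", "end")
    bnd_start <- frag$start[fi]
    bnd_end <- frag$end[fi]
    hit <- rep(NA_integer_, nrow(rd))
    for (side in c("start", "end")) {
      sel <- which(anchors == side)
      if (length(sel) == 0L) next
      bnd <- if (side == "start") bnd_start else bnd_end
      j <- findInterval(p5[sel], bnd)
      d_lo <- ifelse(j >= 1, p5[sel] - bnd[pmax(j, 1L)], Inf)
      d_hi <- ifelse(j < length(bnd), bnd[pmin(j + 1L, length(bnd))] - p5[sel],
                     Inf)
      # nearest boundary wins; exact ties go to the left boundary
      pick <- ifelse(d_lo <= d_hi, pmax(j, 1L), pmin(j + 1L, length(bnd)))
      dist <- pmin(d_lo, d_hi)
      ok <- is.finite(dist) & dist <= end_tolerance
      hit[sel[ok]] <- fi[pick[ok]]
    }
    unassigned <- unassigned + sum(is.na(hit))
    tab <- table(hit[!is.na(hit)])
    idx <- as.integer(names(tab))
    frag$score[idx] <- frag$score[idx] + as.numeric(tab)
  }

  if (!keep_blind) {
    drop <- frag$blind_left & frag$blind_right
    unassigned <- unassigned + sum(frag$score[drop])
    frag <- frag[!drop, , drop = FALSE]
  }
  stopifnot(sum(frag$score) + unassigned == n_reads)
  new_score_track(frag, stage = "raw", unassigned = unassigned)
}

#' Build a raw score track from a precomputed fragment score table
#'
#' Alternative entry point for users starting from deposited processed data:
#' a TSV with columns `chrom`, `start`, `end`, `score` whose intervals match
#' fragments of the map exactly.
#'
#' @param path TSV file path (comment lines starting with `#` are ignored).
#' @param map A `fragment_map`; scored intervals must match its fragments.
#' @param keep_blind Keep fragments blind on both ends? Default `FALSE`.
#' @return A raw `score_track`.
#' @export
read_score_table <- function(path, map, keep_blind = FALSE) {
  stopifnot(inherits(map, "fragment_map"))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(tab)))
  frag <- tibble::as_tibble(map)
  key_map <- paste(frag$chrom, frag$start, frag$end)
  key_tab <- paste(tab$chrom, tab$start, tab$end)
  pos <- match(key_tab, key_map)
  if (anyNA(pos)) {
    stop("score table ", path, " has ", sum(is.na(pos)),
         " interval(s) not present in the fragment map")
  }
  frag$score <- 0
  frag$score[pos] <- tab$score
  if (any(frag$score < 0) || any(!is.finite(frag$score))) {
    stop("scores must be finite and non-negative: ", path)
  }
  if (!keep_blind) {
    frag <- frag[!(frag$blind_left & frag$blind_right), , drop = FALSE]
  }
  new_score_track(frag, stage = "raw")
}

#' Remove fragments around the viewpoint
#'
#' Drops every retained fragment overlapping the exclusion window by at
#' least one base. The self-ligation and undigested signal immediately
#' around the bait dominates raw 4C profiles and must never enter
#' normalization or testing. The operation is idempotent and records the
#' exclusion window, the bait, and the removal count as track metadata.
#'
#' @param track A `score_track`.
#' @param excluded A region tibble (the exclusion window).
#' @param bait Optional bait region; defaults to the exclusion window
#'   itself, whose center then serves as the bait center downstream.
#' @return The track without the overlapping fragments.
#' @export
exclude_viewpoint <- function(track, excluded, bait = NULL) {
  stopifnot(inherits(track, "score_track"), is.data.frame(excluded),
            nrow(excluded) == 1L)
  meta <- track_meta(track)
  if (!excluded$chrom %in% track$chrom) {
    warning("exclusion region on ", excluded$chrom,
            " overlaps no chromosome of the track; track unchanged")
    drop <- rep(FALSE, nrow(track))
  } else {
    drop <- track$chrom == excluded$chrom &
      track$start < excluded$end & track$end > excluded$start
  }
  out <- tibble::as_tibble(track)[!drop, , drop = FALSE]
  new_score_track(out, stage = meta$stage,
                  bait = bait %||% meta$bait %||% excluded,
                  excluded = excluded,
                  unassigned = meta$unassigned,
                  n_removed = (meta$n_removed %||% 0) + sum(drop),
                  norm_mean = meta$norm_mean)
}

#' Write a score track
#'
#' `write_score_table()` writes a TSV (`chrom`, `start`, `end`, `index`,
#' `score`, and `extrapolated` when present) with the processing stage in a
#' comment header. `write_bedgraph()` writes a browser-ready bedGraph at
#' fragment resolution, values formatted to 6 significant digits so reruns
#' are byte-identical.
#'
#' @param track A `score_track`.
#' @param path Destination file.
#' @param name Track name for the bedGraph track line.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(track, path) {
  stopifnot(inherits(track, "score_track"))
  cols <- intersect(c("chrom", "start", "end", "index", "score",
                      "extrapolated"), names(track))
  df <- tibble::as_tibble(track)[, cols]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#stage=%s", track_stage(track)),
               paste(cols, collapse = "\t"),
               do.call(paste, c(lapply(df, function(x) {
                 if (is.numeric(x)) sprintf("%.10g", x) else as.character(x)
               }), sep = "\t"))), con, sep = "\n")
  invisible(path)
}

#' @rdname write_score_table
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  stopifnot(inherits(track, "score_track"))
  hdr <- sprintf('track type=bedGraph name="%s"',
                 name %||% paste0("4C_", track_stage(track)))
  rows <- sprintf("%s\t%d\t%d\t%.6g", track$chrom, as.integer(track$start),
                  as.integer(track$end), track$score)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Read aligned reads from BED or SAM/BAM
#'
#' BED input needs at least `chrom`, `start`, `end`; a sixth column is taken
#' as strand (missing strand defaults to `+`). SAM/BAM input is read through
#' Rsamtools/GenomicAlignments and reduced to reference coordinates; the 5'
#' end used downstream is the leftmost coordinate for plus-strand and the
#' rightmost for minus-strand alignments.
#'
#' @param path Input file (`.bed`, `.sam`, or `.bam`).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @export
read_aligned_reads <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                             stringsAsFactors = FALSE)
    out <- tibble::tibble(chrom = as.character(tab[[1]]),
                          start = as.numeric(tab[[2]]),
                          end = as.numeric(tab[[3]]),
                          strand = if (ncol(tab) >= 6)
                            as.character(tab[[6]]) else "+")
    out$strand[!out$strand %in% c("+", "-")] <- "+"
    return(out)
  }
  if (ext %in% c("sam", "bam")) {
    bam <- path
    if (ext == "sam") {
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    }
    aln <- GenomicAlignments::readGAlignments(bam)
    return(tibble::tibble(
      chrom = as.character(GenomicAlignments::seqnames(aln)),
      start = GenomicAlignments::start(aln) - 1,
      end = as.numeric(GenomicAlignments::end(aln)),
      strand = as.character(GenomicAlignments::strand(aln))))
  }
  stop("unsupported read format: .", ext, " (expected .bed, .sam or .bam)")
}
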