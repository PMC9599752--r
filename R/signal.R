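#' Signal-processing parameters
#'
#' @param norm_halfwidth Half-width (bases) of the normalization window
#'   around the bait center; default 1 Mb, i.e. scores are divided by the
#'   mean fragment score within +/- 1 Mb of the bait.
#' @param smooth_window Running-mean window in fragments; odd, default 11.
#' @param fit_min_distance,fit_max_distance Distance range (bases from the
#'   bait center) over which the decay model is fitted; defaults 5 kb
#'   (beyond the excluded viewpoint) to 2 Mb (cis TAD scale).
#' @return A list of class `signal_params`.
#' @export
signal_params <- function(norm_halfwidth = 1e6, smooth_window = 11,
                          fit_min_distance = 5e3, fit_max_distance = 2e6) {
  stopifnot(norm_halfwidth > 0,
            smooth_window >= 1, smooth_window %% 2 == 1,
            fit_min_distance > 0, fit_max_distance > fit_min_distance)
  structure(list(norm_halfwidth = norm_halfwidth,
                 smooth_window = as.integer(smooth_window),
                 fit_min_distance = fit_min_distance,
                 fit_max_distance = fit_max_distance),
            class = c("signal_params", "list"))
}

bait_center_of <- function(track, bait) {
  bait <- bait %||% attr(track, "bait")
  if (is.null(bait)) {
    stop("no bait region: pass `bait=` or apply exclude_viewpoint() first")
  }
  list(chrom = bait$chrom, center = region_center(bait))
}

#' Normalize fragment scores to the local mean around the bait
#'
#' Divides every fragment score by the mean score of retained fragments
#' whose midpoints fall within `norm_halfwidth` of the bait center (on the
#' bait chromosome). After normalization the in-window mean is exactly 1,
#' which puts replicates of different sequencing depth on a common scale.
#'
#' @param track A raw `score_track` (viewpoint exclusion already applied).
#' @param params A [signal_params()] list.
#' @param bait Optional bait region; defaults to the track's bait metadata.
#' @return A `score_track` at stage `normalized`.
#' @export
normalize_local_mean <- function(track, params = signal_params(),
                                 bait = NULL) {
  assert_stage(track, "raw", "normalize_local_mean")
  b <- bait_center_of(track, bait)
  mid <- track_midpoint(track)
  in_win <- track$chrom == b$chrom &
    mid >= b$center - params$norm_halfwidth &
    mid <= b$center + params$norm_halfwidth
  win_label <- sprintf("%s:%.0f-%.0f", b$chrom,
                       b$center - params$norm_halfwidth,
                       b$center + params$norm_halfwidth)
  if (!any(in_win)) {
    stop("normalization window ", win_label, " contains no retained fragment")
  }
  m <- mean(track$score[in_win])
  if (!is.finite(m) || m <= 0) {
    stop("mean fragment score in normalization window ", win_label,
         " is ", m, "; cannot normalize")
  }
  meta <- track_meta(track)
  out <- tibble::as_tibble(track)
  out$score <- out$score / m
  new_score_track(out, stage = "normalized", bait = attr(track, "bait"),
                  excluded = meta$excluded, unassigned = meta$unassigned,
                  n_removed = meta$n_removed, norm_mean = m)
}

#' Smooth a score track with a running mean
#'
#' Replaces each score by the mean over a centered window of
#' `smooth_window` fragments in fragment order, per chromosome. At
#' chromosome edges the window truncates to the available fragments (so a
#' window spanning the whole chromosome returns the grand mean everywhere).
#' Smoothed tracks are for visualization; differential testing uses
#' unsmoothed scores to avoid inducing dependence between fragments.
#'
#' @param track A `score_track` at stage `normalized`.
#' @param params A [signal_params()] list; `smooth_window` is used.
#' @return A `score_track` at stage `smoothed`, same length.
#' @export
running_mean <- function(track, params = signal_params()) {
  assert_stage(track, "normalized", "running_mean")
  k <- (params$smooth_window - 1L) %/% 2L
  meta <- track_meta(track)
  out <- tibble::as_tibble(track)
  for (chr in unique(out$chrom)) {
    sel <- which(out$chrom == chr)
    x <- out$score[sel]
    n <- length(x)
    cs <- c(0, cumsum(x))
    i <- seq_len(n)
    lo <- pmax(1L, i - k)
    hi <- pmin(n, i + k)
    out$score[sel] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  new_score_track(out, stage = "smoothed", bait = meta$bait,
                  excluded = meta$excluded, unassigned = meta$unassigned,
                  n_removed = meta$n_removed, norm_mean = meta$norm_mean)
}

#' Fit the contact distance-decay model
#'
#' Contact frequency falls off with genomic distance roughly as a power law;
#' the model is `log10(score) = a - log10(d)`, a line of fixed slope -1 in
#' log-log space, where `d` is the distance from the bait center to the
#' fragment midpoint. With the slope fixed, the least-squares intercept has
#' the closed form `a = mean(log10(score) + log10(d))` over eligible
#' fragments: cis fragments with positive score and `d` inside the fit
#' range. Zero-score fragments are excluded (log undefined).
#'
#' @param track A `score_track` at stage `normalized`.
#' @param params A [signal_params()] list; the fit range is used.
#' @param bait Optional bait region; defaults to track metadata.
#' @return A `decay_fit` with fields `intercept`, `slope` (fixed at -1),
#'   `se` (standard error of the intercept), `n_points`, `fit_range`,
#'   `chrom`, `bait_center`.
#' @export
fit_decay <- function(track, params = signal_params(), bait = NULL) {
  assert_stage(track, "normalized", "fit_decay")
  b <- bait_center_of(track, bait)
  cis <- track$chrom == b$chrom
  d <- abs(track_midpoint(track) - b$center)
  elig <- cis & track$score > 0 & d >= params$fit_min_distance &
    d <= params$fit_max_distance
  n <- sum(elig)
  if (n < 2L) {
    stop("decay fit needs at least 2 cis fragments with positive score in ",
         "the distance range [", params$fit_min_distance, ", ",
         params$fit_max_distance, "]; found ", n)
  }
  x <- log10(track$score[elig]) + log10(d[elig])
  structure(list(intercept = mean(x), slope = -1,
                 se = stats::sd(x) / sqrt(n), n_points = n,
                 fit_range = c(params$fit_min_distance,
                               params$fit_max_distance),
                 chrom = b$chrom, bait_center = b$center),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(paste0("<decay_fit> log10(score) = %.4f - log10(d)",
                     "  [n = %d, se = %.2g, d in %.3g-%.3g bp]\n"),
              x$intercept, x$n_points, x$se, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Correct a track for the contact distance-decay profile
#'
#' Divides each normalized cis fragment score by the expected score under
#' the fitted decay model, `expected(d) = 10^intercept / d`, so that
#' distance-independent enrichment (an enhancer--promoter loop) stands out
#' as values above 1. Zero observed scores stay 0 (signal absence). Trans
#' fragments are dropped: a distance model is undefined off the bait
#' chromosome. Fragments closer than the fit range carry an `extrapolated`
#' flag.
#'
#' @param track A `score_track` at stage `normalized`, same lineage as the
#'   fit.
#' @param fit A `decay_fit` from [fit_decay()].
#' @return A `score_track` at stage `profile_corrected` with an
#'   `extrapolated` column.
#' @export
profile_correct <- function(track, fit) {
  assert_stage(track, "normalized", "profile_correct")
  stopifnot(inherits(fit, "decay_fit"))
  meta <- track_meta(track)
  out <- tibble::as_tibble(track)
  out <- out[out$chrom == fit$chrom, , drop = FALSE]
  d <- (out$start + out$end) / 2 - fit$bait_center
  d <- abs(d)
  if (any(d == 0)) {
    stop("fragment at zero distance from the bait center: ",
         "viewpoint exclusion appears to have been skipped")
  }
  expected <- 10^fit$intercept / d
  out$score <- ifelse(out$score == 0, 0, out$score / expected)
  out$extrapolated <- d < fit$fit_range[1]
  new_score_track(out, stage = "profile_corrected", bait = meta$bait,
                  excluded = meta$excluded, unassigned = meta$unassigned,
                  n_removed = meta$n_removed, norm_mean = meta$norm_mean)
}

#' Process a raw track through every stage
#'
#' Convenience wrapper chaining [exclude_viewpoint()],
#' [normalize_local_mean()], [running_mean()], [fit_decay()] and
#' [profile_correct()] for one replicate.
#'
#' @param raw A raw `score_track`.
#' @param excluded Viewpoint exclusion region.
#' @param params A [signal_params()] list.
#' @param bait Optional bait region (defaults to the exclusion window).
#' @return A named list: `raw`, `normalized`, `smoothed`,
#'   `profile_corrected` tracks and the `decay_fit`.
#' @export
process_replicate <- function(raw, excluded, params = signal_params(),
                              bait = NULL) {
  tr <- exclude_viewpoint(raw, excluded, bait = bait)
  nrm <- normalize_local_mean(tr, params)
  fit <- fit_decay(nrm, params)
  list(raw = tr, normalized = nrm, smoothed = running_mean(nrm, params),
       profile_corrected = profile_correct(nrm, fit), decay_fit = fit)
}
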