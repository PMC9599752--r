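#' Plot a score track
#'
#' Fragment-resolution step plot of scores along the chromosome, optionally
#' highlighting a region of interest (e.g. a candidate enhancer element).
#'
#' @param object A `score_track`.
#' @param highlight Optional one-row region tibble drawn as a shaded band.
#' @param log_y Log-scale the y axis? Default `FALSE`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.score_track <- function(object, highlight = NULL, log_y = FALSE,
                                 ...) {
  df <- tibble::as_tibble(object)
  df$midpoint <- (df$start + df$end) / 2
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$midpoint,
                                        y = .data$score)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "fragment score",
                  title = paste0("4C score track (",
                                 track_stage(object), ")")) +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::annotate("rect", xmin = highlight$start,
                               xmax = highlight$end, ymin = -Inf,
                               ymax = Inf, alpha = 0.2, fill = "orange")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the distance-decay fit
#'
#' Log-log scatter of normalized score against distance from the bait
#' center, with the fitted fixed-slope line overlaid.
#'
#' @param object A `decay_fit`.
#' @param track The normalized `score_track` the fit was computed on.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, track, ...) {
  stopifnot(inherits(track, "score_track"))
  df <- tibble::as_tibble(track)
  df <- df[df$chrom == object$chrom, , drop = FALSE]
  df$d <- abs((df$start + df$end) / 2 - object$bait_center)
  df <- df[df$score > 0 & df$d > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept, slope = -1,
                         colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from bait (bp)", y = "normalized score",
                  title = sprintf("distance decay: log10 s = %.3f - log10 d",
                                  object$intercept)) +
    ggplot2::theme_minimal()
}

#' Long-format region score table for boxplots
#'
#' Pools region fragment scores per condition, replicate, and stage into a
#' long tibble, the shape needed for condition-vs-condition boxplots of
#' normalized and profile-corrected scores.
#'
#' @inheritParams compare_conditions
#' @return A tibble with columns `condition`, `replicate`, `stage`,
#'   `score`.
#' @export
region_score_table <- function(cond_a, cond_b, region,
                               stages = c("normalized",
                                          "profile_corrected"),
                               condition_names = c("A", "B")) {
  conds <- stats::setNames(list(as_replicate_list(cond_a),
                                as_replicate_list(cond_b)),
                           condition_names)
  purrr::imap(conds, function(reps, cname) {
    purrr::imap(reps, function(rep_tracks, ri) {
      purrr::map(stages, function(st) {
        tr <- pick_stage(rep_tracks, st)
        if (is.null(tr)) {
          stop("stage '", st, "' missing from condition ", cname,
               " replicate ", ri)
        }
        v <- suppressWarnings(extract_region_scores(tr, region))
        if (length(v) == 0L) return(NULL)
        tibble::tibble(condition = cname, replicate = ri, stage = st,
                       score = v)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Boxplot of region contact scores by condition
#'
#' Side-by-side boxplots of pooled region fragment scores per condition,
#' faceted by processing stage -- the standard display for a two-condition
#' 4C contact comparison.
#'
#' @inheritParams region_score_table
#' @return A ggplot object.
#' @export
plot_contact_boxplot <- function(cond_a, cond_b, region,
                                 stages = c("normalized",
                                            "profile_corrected"),
                                 condition_names = c("A", "B")) {
  df <- region_score_table(cond_a, cond_b, region, stages, condition_names)
  df$stage <- factor(df$stage, levels = stages)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$score,
                                   fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~stage, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "fragment score",
                  title = paste0("contacts in ",
                                 region$name %||% format_region(region))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
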