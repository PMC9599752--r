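#' Statistical-testing parameters
#'
#' @param alpha Significance level for the normality gate; default 0.05.
#' @param star_thresholds Strictly decreasing p-value thresholds mapped to
#'   `*`, `**`, `***`, `****`. Defaults `0.05, 0.01, 0.001, 0.0001`: the
#'   first three are strict (`p < t`), the last is inclusive
#'   (`p <= 0.0001`).
#' @param exact_max_n Largest group size for which the exact (enumeration)
#'   Mann-Whitney p-value is used when there are no ties; default 8.
#' @return A list of class `stats_params`.
#' @export
stats_params <- function(alpha = 0.05,
                         star_thresholds = c(0.05, 0.01, 0.001, 0.0001),
                         exact_max_n = 8) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1,
            length(star_thresholds) == 4L,
            all(diff(star_thresholds) < 0),
            exact_max_n >= 1)
  structure(list(alpha = alpha, star_thresholds = star_thresholds,
                 exact_max_n = as.integer(exact_max_n)),
            class = c("stats_params", "list"))
}

#' Map a p-value to significance stars
#'
#' A pure, monotone mapping: `*` for `p < 0.05`, `**` for `p < 0.01`,
#' `***` for `p < 0.001`, `****` for `p <= 0.0001`, `ns` otherwise
#' (default thresholds).
#'
#' @param p A vector of p-values in `[0, 1]`.
#' @param thresholds Strictly decreasing length-4 thresholds.
#' @return A character vector of star labels.
#' @examples
#' p_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5))
#' @export
p_stars <- function(p, thresholds = c(0.05, 0.01, 0.001, 0.0001)) {
  stopifnot(length(thresholds) == 4L, all(diff(thresholds) < 0),
            all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < thresholds[1]] <- "*"
  out[p < thresholds[2]] <- "**"
  out[p < thresholds[3]] <- "***"
  out[p <= thresholds[4]] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Extract the scores of fragments inside a region
#'
#' Returns the scores of retained fragments whose midpoints lie within the
#' region (half-open), in fragment order.
#'
#' @param track A `score_track`.
#' @param region A one-row region tibble on the track's chromosome.
#' @return A numeric score vector (empty, with a warning, when no fragment
#'   midpoint falls in the region).
#' @export
extract_region_scores <- function(track, region) {
  stopifnot(inherits(track, "score_track"), is.data.frame(region),
            nrow(region) == 1L)
  sel <- track$chrom == region$chrom
  mid <- track_midpoint(track)
  sel <- sel & mid >= region$start & mid < region$end
  if (!any(sel)) {
    warning("no retained fragment midpoint in region ",
            format_region(region))
    return(numeric(0))
  }
  scores <- track$score[sel]
  scores[order(track$index[sel])]
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z into
#' `K2 = z_skew^2 + z_kurt^2`, referred to a chi-square distribution with
#' 2 degrees of freedom. Used here as an advisory gate: rejection justifies
#' the nonparametric Mann-Whitney comparison; the comparison runs either
#' way.
#'
#' @param x Numeric sample. Samples below 8 values yield a not-applicable
#'   result (all-`NA` statistics) with a warning rather than an error; zero
#'   variance is an error (moments undefined).
#' @return A one-row tibble: `n`, `skew_z`, `kurt_z`, `statistic`,
#'   `p_value`, `applicable`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  stopifnot(all(is.finite(x)))
  n <- length(x)
  if (n < 8L) {
    warning("D'Agostino-Pearson test needs n >= 8 (got ", n,
            "); returning not-applicable result")
    return(tibble::tibble(n = n, skew_z = NA_real_, kurt_z = NA_real_,
                          statistic = NA_real_, p_value = NA_real_,
                          applicable = FALSE))
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance input: normality test undefined")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # D'Agostino (1970) transformed skewness
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  y_a <- y / alpha
  z_skew <- delta * log(y_a + sqrt(y_a^2 + 1))

  # Anscombe-Glynn (1983) transformed kurtosis
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * (abs((1 - 2 / a) / denom))^(1 / 3)
  z_kurt <- ((1 - 2 / (9 * a)) - term2) / sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  tibble::tibble(n = n, skew_z = z_skew, kurt_z = z_kurt, statistic = k2,
                 p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
                 applicable = TRUE)
}

#' Unpaired two-tailed Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. For tie-free data
#' with both group sizes at most `exact_max_n`, the two-tailed p-value is
#' exact -- the probability, over all equally likely rank assignments, of a
#' U at least as far from its null mean `n1*n2/2` as observed. Otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y Numeric score vectors for the two groups (non-empty).
#' @param params A [stats_params()] list.
#' @return A one-row tibble of class `contact_test`: `n1`, `n2`, `U`
#'   (for group `x`), `p_two_tailed`, `method` (`"exact"` or
#'   `"normal_approx"`), `stars`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, params = stats_params()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  m <- n1 * n2 / 2
  dev <- abs(u1 - m)

  if (!ties && max(n1, n2) <= params$exact_max_n) {
    support <- 0:(n1 * n2)
    probs <- stats::dwilcox(support, n1, n2)
    p <- sum(probs[abs(support - m) >= dev - 1e-9])
    method <- "exact"
  } else {
    nn <- n1 + n2
    tie_counts <- table(r)
    sigma2 <- n1 * n2 / 12 *
      ((nn + 1) - sum(tie_counts^3 - tie_counts) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, dev - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal_approx"
  }
  p <- min(1, p)
  out <- tibble::tibble(n1 = n1, n2 = n2, U = u1, p_two_tailed = p,
                        method = method,
                        stars = p_stars(p, params$star_thresholds))
  class(out) <- unique(c("contact_test", class(out)))
  out
}

#' Differential contact test between two conditions in a target region
#'
#' For each requested processing stage, pools the region's fragment scores
#' across replicates within each condition (fragments are the sampling
#' unit), runs the D'Agostino-Pearson gate on each pooled group, then an
#' unpaired two-tailed Mann-Whitney test, and attaches significance stars.
#'
#' @param cond_a,cond_b Replicates per condition: a list whose elements are
#'   either a single `score_track` or a list of stage-labelled
#'   `score_track`s for one replicate. Each replicate must provide every
#'   requested stage.
#' @param region A one-row region tibble (the analyzed target region).
#' @param params A [stats_params()] list.
#' @param stages Stages to test; default `normalized` and
#'   `profile_corrected`.
#' @param condition_names Labels for the two conditions.
#' @return A tibble of class `contact_test`, one row per stage, with region
#'   coordinates, group sizes, `U`, `p_two_tailed`, the per-group normality
#'   gate (`normality_p_a/b`, `normality_rejected_a/b`), and `stars`.
#' @export
compare_conditions <- function(cond_a, cond_b, region,
                               params = stats_params(),
                               stages = c("normalized", "profile_corrected"),
                               condition_names = c("A", "B")) {
  stopifnot(is.data.frame(region), nrow(region) == 1L)
  conds <- list(as_replicate_list(cond_a), as_replicate_list(cond_b))
  names(conds) <- condition_names

  rows <- purrr::map(stages, function(stage) {
    pools <- purrr::imap(conds, function(reps, cname) {
      scores <- purrr::imap(reps, function(rep_tracks, i) {
        tr <- pick_stage(rep_tracks, stage)
        if (is.null(tr)) {
          stop("stage '", stage, "' missing from condition ", cname,
               " replicate ", i)
        }
        extract_region_scores(tr, region)
      })
      unlist(scores, use.names = FALSE)
    })
    if (any(lengths(pools) < 2L)) {
      stop("fewer than 2 region fragment scores in a pooled group for ",
           "region ", format_region(region), " at stage ", stage)
    }
    gate <- purrr::map(pools, function(v) {
      if (stats::var(v) == 0) {
        tibble::tibble(p_value = NA_real_, applicable = FALSE)
      } else {
        suppressWarnings(dagostino_pearson(v))
      }
    })
    mw <- mann_whitney_u(pools[[1]], pools[[2]], params)
    tibble::tibble(
      region_name = region$name, chrom = region$chrom,
      start = region$start, end = region$end, stage = stage,
      n1 = mw$n1, n2 = mw$n2, U = mw$U, p_two_tailed = mw$p_two_tailed,
      method = mw$method,
      normality_p_a = gate[[1]]$p_value, normality_p_b = gate[[2]]$p_value,
      normality_rejected_a = isTRUE(gate[[1]]$applicable) &&
        !is.na(gate[[1]]$p_value) && gate[[1]]$p_value < params$alpha,
      normality_rejected_b = isTRUE(gate[[2]]$applicable) &&
        !is.na(gate[[2]]$p_value) && gate[[2]]$p_value < params$alpha,
      stars = mw$stars)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "conditions") <- condition_names
  class(out) <- unique(c("contact_test", class(out)))
  out
}

as_replicate_list <- function(x) {
  if (inherits(x, "score_track")) return(list(list(x)))
  stopifnot(is.list(x), length(x) >= 1L)
  purrr::map(x, function(el) {
    if (inherits(el, "score_track")) list(el) else el
  })
}

pick_stage <- function(tracks, stage) {
  for (tr in tracks) {
    if (inherits(tr, "score_track") && identical(track_stage(tr), stage)) {
      return(tr)
    }
  }
  NULL
}
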