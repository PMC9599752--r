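#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Ignored.
#' @return One row per model term (`intercept`, `slope`); the slope is
#'   fixed, not estimated, so its standard error is `NA`.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$se, NA_real_),
                 fixed = c(FALSE, TRUE))
}

#' @rdname tidy.decay_fit
#' @return `glance()` returns a one-row model summary.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope, se = x$se,
                 n_points = x$n_points, fit_min = x$fit_range[1],
                 fit_max = x$fit_range[2])
}

#' Tidy differential contact test results
#'
#' @param x A `contact_test` tibble.
#' @param ... Ignored.
#' @return `tidy()` returns the underlying tibble; `glance()` a one-row
#'   summary (number of tests, smallest p-value and its stage).
#' @export
tidy.contact_test <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.contact_test
#' @export
glance.contact_test <- function(x, ...) {
  i <- which.min(x$p_two_tailed)
  tibble::tibble(n_tests = nrow(x), min_p = x$p_two_tailed[i],
                 min_p_stage = x$stage[i] %||% NA_character_,
                 stars = x$stars[i])
}
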