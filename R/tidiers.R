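# broom-style accessors for the fitted law objects.

#' Tidy a fitted parabola
#'
#' @param x A [fit_parabola()] result.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`x^2`, `x`,
#'   `(Intercept)`) and their least-squares estimates.
#' @export
tidy.parabolic_fit <- function(x, ...) {
  tibble(term = c("x^2", "x", "(Intercept)"),
         estimate = c(x$a, x$b, x$c))
}

#' @rdname tidy.parabolic_fit
#' @return `glance()` returns a one-row tibble with `r.squared`, `x.peak`,
#'   `upward`, `law`, `nobs`.
#' @export
glance.parabolic_fit <- function(x, ...) {
  tibble(r.squared = x$r2, x.peak = x$x_peak, upward = x$upward,
         law = x$law, nobs = x$n)
}

#' Tidy a fitted line
#'
#' @param x A [fit_line()] result.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`x`, `(Intercept)`).
#' @export
tidy.linear_fit <- function(x, ...) {
  tibble(term = c("x", "(Intercept)"),
         estimate = c(x$slope, x$intercept))
}

#' @rdname tidy.linear_fit
#' @return `glance()` returns a one-row tibble with `r.squared`, `law`,
#'   `nobs`.
#' @export
glance.linear_fit <- function(x, ...) {
  tibble(r.squared = x$r2, law = x$law, nobs = x$n)
}

#' @export
tidy.law_class <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$parabola), model = "parabola"),
    dplyr::mutate(tidy(x$line), model = "line")
  )
}

#' @export
glance.law_class <- function(x, ...) {
  tibble(class = x$class, p.quadratic = x$p_quadratic,
         parabola.r.squared = x$parabola$r2, line.r.squared = x$line$r2,
         x.peak = x$parabola$x_peak, nobs = x$parabola$n)
}

#' @export
glance.fixture_report <- function(x, ...) {
  tibble(n_rows = x$n_rows, n_consistent = x$n_consistent, pass = x$pass)
}
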