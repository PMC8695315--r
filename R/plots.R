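# ggplot2 presentation layer. Each law gets a scatter-plus-fitted-curve
# panel in the style of the published figures: points are snapshots, the
# curve is the least-squares law, the dashed vertical line marks the peak.

law_curve_data <- function(fit, n = 200) {
  x <- seq(fit$x_range[1], fit$x_range[2], length.out = n)
  y <- if (inherits(fit, "parabolic_fit")) {
    fit$a * x^2 + fit$b * x + fit$c
  } else {
    fit$slope * x + fit$intercept
  }
  tibble(x = x, y = y)
}

#' Plot a fitted law over its data
#'
#' `plot_segl()` draws the energy gap law (ln Rate vs driving force),
#' `plot_exdl()` the extended Dutton law (ln Rate vs distance, with the
#' selected parabolic or linear candidate), and `plot_esrc()` the
#' distance--energy relation. Peaks are marked with a dashed line and the
#' subtitle carries the coefficients and \eqn{R^2} as in published insets.
#'
#' @param data A snapshot table with `rc_nm`, `neg_sfeg_ev`, `ln_rate`.
#' @param fit Optionally a pre-computed fit; refitted from `data` if `NULL`.
#' @return A ggplot object.
#' @export
plot_segl <- function(data, fit = NULL) {
  fit <- fit %||% fit_segl(data)
  law_panel(data$neg_sfeg_ev, data$ln_rate, fit,
            xlab = expression(-Delta * G^0 ~ "(eV)"),
            ylab = expression(ln ~ "Rate (rate in" ~ ps^-1 * ")"),
            title = "Energy gap law")
}

#' @rdname plot_segl
#' @param ... Passed to [classify_relationship()].
#' @export
plot_exdl <- function(data, fit = NULL, ...) {
  cls <- fit %||% fit_exdl(data, ...)
  use <- if (cls$class == "parabolic") cls$parabola else cls$line
  law_panel(data$rc_nm, data$ln_rate, use,
            xlab = expression(R[c] ~ "(nm)"),
            ylab = expression(ln ~ "Rate (rate in" ~ ps^-1 * ")"),
            title = paste0("Extended Dutton law (", cls$class, ")"))
}

#' @rdname plot_segl
#' @export
plot_esrc <- function(data, fit = NULL) {
  fit <- fit %||% fit_esrc(data)
  law_panel(data$rc_nm, data$neg_sfeg_ev, fit,
            xlab = expression(R[c] ~ "(nm)"),
            ylab = expression(-Delta * G^0 ~ "(eV)"),
            title = "Distance-energy relation")
}

law_panel <- function(x, y, fit, xlab, ylab, title) {
  pts <- tibble(x = x, y = y)
  crv <- law_curve_data(fit)
  sub <- if (inherits(fit, "parabolic_fit")) {
    sprintf("y = %.3g x² %+.3g x %+.3g,  R² = %.3f",
            fit$a, fit$b, fit$c, fit$r2)
  } else {
    sprintf("y = %.3g x %+.3g,  R² = %.3f",
            fit$slope, fit$intercept, fit$r2)
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = crv, colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = xlab, y = ylab, title = title, subtitle = sub) +
    ggplot2::theme_minimal()
  peak <- if (inherits(fit, "parabolic_fit")) fit$x_peak else NA_real_
  if (!is.na(peak)) {
    p <- p + ggplot2::geom_vline(xintercept = peak, linetype = "dashed")
  }
  p
}

#' @export
autoplot.parabolic_fit <- function(object, data = NULL, ...) {
  pts <- if (!is.null(data)) data else {
    mf <- stats::model.frame(object$lm)
    tibble(x = mf[["x"]], y = mf[["y"]])
  }
  law_panel(pts$x, pts$y, object, xlab = "x", ylab = "y",
            title = paste0("Parabolic fit (", object$law, ")"))
}

#' @export
autoplot.linear_fit <- function(object, data = NULL, ...) {
  pts <- if (!is.null(data)) data else {
    mf <- stats::model.frame(object$lm)
    tibble(x = mf[["x"]], y = mf[["y"]])
  }
  law_panel(pts$x, pts$y, object, xlab = "x", ylab = "y",
            title = paste0("Linear fit (", object$law, ")"))
}

#' @export
autoplot.synthetic_dataset <- function(object, ...) {
  s <- object$snapshots
  ggplot2::ggplot(s, ggplot2::aes(x = .data$time_ps, y = .data$rc_nm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$spec$rc_mean,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "time (ps)", y = expression(R[c] ~ "(nm)"),
                  title = "Synthetic donor-acceptor distance trajectory") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.equivalence_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$xm_es, y = .data$xm_esrc,
                               colour = .data$agrees)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(X[m](ES) ~ "(eV)"),
                  y = expression(X[m](ESRc) ~ "(eV)"),
                  title = "Peak equivalence across axes") +
    ggplot2::theme_minimal()
}
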