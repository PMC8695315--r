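# Fitting of the three empirical laws:
#   SEGL  (energy gap law)        ln Rate vs -SFEG, parabola, vertex X_m(ES)
#   EXDL  (extended Dutton law)   ln Rate vs Rc, parabola or line, vertex X_m(Rc)
#   ESRC  (distance-energy line)  -SFEG vs Rc, line
# All fits are unweighted ordinary least squares through stats::lm.

#' Ordinary least-squares parabola fit
#'
#' Fits \eqn{y = a x^2 + b x + c} and extracts the vertex \eqn{-b/(2a)}. The
#' vertex is reported only for a downward parabola (\eqn{a < 0}); an upward
#' one carries `x_peak = NA` and a warning flag.
#'
#' @param x,y Numeric vectors of equal length >= 3 with >= 3 distinct `x`.
#' @param law Label stored on the fit (`"SEGL"`, `"EXDL"`, or free text).
#' @return An object of class `parabolic_fit`: list with `a`, `b`, `c`,
#'   `r2`, `x_peak`, `upward` (flag), `law`, `n`, `x_range`.
#' @examples
#' f <- fit_parabola(c(0, 1, 2, 3), c(-1, 1, -1, -7))
#' f$x_peak
#' @seealso [fit_line()], [peak_location()], [tidy()], [glance()]
#' @export
fit_parabola <- function(x, y, law = "SEGL") {
  check_xy(x, y, min_n = 3)
  if (length(unique(x)) < 3) {
    abort("Degenerate parabola fit: need >= 3 distinct x values.")
  }
  fit <- lm(y ~ x + I(x^2))
  cf <- coef(fit)
  if (any(!is.finite(cf))) {
    abort("Degenerate parabola fit: rank-deficient design.")
  }
  a <- unname(cf[["I(x^2)"]]); b <- unname(cf[["x"]])
  c0 <- unname(cf[["(Intercept)"]])
  structure(
    list(
      a = a, b = b, c = c0,
      r2 = determination_coefficient(y, stats::fitted(fit)),
      x_peak = if (a < 0) -b / (2 * a) else NA_real_,
      upward = a > 0,
      law = law, n = length(x), x_range = range(x),
      lm = fit
    ),
    class = "parabolic_fit"
  )
}

#' Ordinary least-squares line fit
#'
#' Fits \eqn{y = B x + C} with the determination coefficient.
#'
#' @param x,y Numeric vectors of equal length >= 2 with >= 2 distinct `x`.
#' @param law Label stored on the fit (`"ESRC"`, `"EXDL-linear"`, free text).
#' @return An object of class `linear_fit`: list with `slope`, `intercept`,
#'   `r2`, `law`, `n`, `x_range`.
#' @export
fit_line <- function(x, y, law = "ESRC") {
  check_xy(x, y, min_n = 2)
  if (length(unique(x)) < 2) {
    abort("Degenerate line fit: all x values identical.")
  }
  fit <- lm(y ~ x)
  cf <- coef(fit)
  structure(
    list(
      slope = unname(cf[["x"]]), intercept = unname(cf[["(Intercept)"]]),
      r2 = determination_coefficient(y, stats::fitted(fit)),
      law = law, n = length(x), x_range = range(x),
      lm = fit
    ),
    class = "linear_fit"
  )
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < min_n) {
    abort(paste0("Need at least ", min_n, " points."))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  invisible(TRUE)
}

#' @export
print.parabolic_fit <- function(x, ...) {
  cat(sprintf("<parabolic_fit %s> y = %.4g x^2 %+.4g x %+.4g  (R^2 = %.4f, n = %d)\n",
              x$law, x$a, x$b, x$c, x$r2, x$n))
  if (!is.na(x$x_peak)) {
    cat(sprintf("  peak x = %.4f (displays %.2f)\n", x$x_peak,
                round(x$x_peak, 2)))
  } else if (x$upward) {
    cat("  upward parabola: no peak\n")
  }
  invisible(x)
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit %s> y = %.4g x %+.4g  (R^2 = %.4f, n = %d)\n",
              x$law, x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Vertex of a fitted parabola
#'
#' Returns \eqn{x_{peak} = -b/(2a)}, the location of the extremum of
#' \eqn{y = a x^2 + b x + c}. For the energy gap law this is the driving
#' force \eqn{X_m(ES)} at the rate maximum; for the parabolic extended
#' Dutton law it is the distance \eqn{X_m(Rc)}. A positive `a` (upward
#' parabola, a rate minimum) triggers a warning. Full precision is returned;
#' display rounding to 2 decimals is the caller's choice.
#'
#' @param a,b Quadratic and linear coefficients; `a` must be non-zero.
#' @return The vertex location.
#' @examples
#' peak_location(-26.1, 40.3) # 0.772...
#' @export
peak_location <- function(a, b) {
  if (any(a == 0)) abort("Undefined peak: quadratic coefficient is zero.")
  if (any(a > 0)) warn("Upward parabola: the extremum is a minimum.")
  -b / (2 * a)
}

#' Determination coefficient
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} of predictions `y_hat` against
#' observations `y`. Equals 1 for a perfect fit and 0 for the mean
#' predictor; it can be negative for predictions worse than the mean and is
#' reported as such, not clamped.
#'
#' @param y,y_hat Numeric vectors of equal length >= 2.
#' @return \eqn{R^2}.
#' @export
determination_coefficient <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 2) {
    abort("`y` and `y_hat` must have equal length >= 2.")
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("Undefined R^2: zero variance in `y`.")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Classify a rate--distance profile as parabolic, linear or featureless
#'
#' Fits both a line and a parabola and applies the decision rule used for
#' extended-Dutton-law profiles: the profile is `"parabolic"` when the
#' quadratic term is significant (partial F-test at `alpha`), the parabola
#' opens downward, and its vertex lies within or adjacent to the observed
#' `x` range (within half the range width beyond either end); otherwise
#' `"linear"` when the line's \eqn{R^2} reaches `r2_min`; otherwise
#' `"none"`. The thresholds quantify a by-inspection classification and are
#' exposed as arguments.
#'
#' @param x,y Numeric vectors, length >= 4.
#' @param alpha Significance level of the partial F-test for the quadratic
#'   term (default 0.05).
#' @param r2_min Minimum linear \eqn{R^2} for the `"linear"` verdict
#'   (default 0.2).
#' @return An object of class `law_class`: list with `class` (one of
#'   `"parabolic"`, `"linear"`, `"none"`), `parabola` ([fit_parabola()]
#'   result), `line` ([fit_line()] result) and `p_quadratic`.
#' @export
classify_relationship <- function(x, y, alpha = 0.05, r2_min = 0.2) {
  check_xy(x, y, min_n = 4)
  parab <- fit_parabola(x, y, law = "EXDL")
  line <- fit_line(x, y, law = "EXDL-linear")
  p_quad <- anova(line$lm, parab$lm)[["Pr(>F)"]][2]
  half_width <- diff(range(x)) / 2
  vertex_ok <- !is.na(parab$x_peak) &&
    parab$x_peak >= min(x) - half_width &&
    parab$x_peak <= max(x) + half_width
  cls <- if (is.finite(p_quad) && p_quad < alpha && parab$a < 0 && vertex_ok) {
    "parabolic"
  } else if (line$r2 >= r2_min) {
    "linear"
  } else {
    "none"
  }
  structure(list(class = cls, parabola = parab, line = line,
                 p_quadratic = p_quad),
            class = "law_class")
}

#' @export
print.law_class <- function(x, ...) {
  cat(sprintf("<law_class> %s (p_quadratic = %.3g, line R^2 = %.3f)\n",
              x$class, x$p_quadratic, x$line$r2))
  invisible(x)
}

#' Partition snapshots into inverted and normal regions
#'
#' On the energy axis the inverted region holds snapshots whose driving
#' force \eqn{-\Delta G^0} exceeds the energy-gap-law vertex \eqn{X_m(ES)};
#' on the distance axis it holds snapshots whose distance falls below the
#' extended-Dutton-law vertex \eqn{X_m(Rc)} (rates slow down as the pair
#' approaches). Values equal to the threshold count as normal.
#'
#' @param values Numeric vector of \eqn{-\Delta G^0} (eV, `axis = "energy"`)
#'   or distances (nm, `axis = "distance"`); non-empty.
#' @param threshold The vertex on that axis; finite.
#' @param axis `"energy"` or `"distance"`.
#' @return An object of class `region_partition`: list with `axis`,
#'   `threshold`, `labels` (character, `"inverted"`/`"normal"` per value),
#'   `fraction_inverted`, `fraction_normal`.
#' @examples
#' region_partition(seq(0.64, 0.80, 0.02), 0.82, "distance")$fraction_inverted
#' @export
region_partition <- function(values, threshold,
                             axis = c("energy", "distance")) {
  axis <- match.arg(axis)
  if (length(values) == 0) abort("`values` must be non-empty.")
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  inverted <- if (axis == "energy") values > threshold else values < threshold
  labels <- ifelse(inverted, "inverted", "normal")
  structure(
    list(axis = axis, threshold = threshold, labels = labels,
         fraction_inverted = mean(inverted),
         fraction_normal = mean(!inverted)),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %s axis, threshold %.4g: %.1f%% inverted, %.1f%% normal (n = %d)\n",
              x$axis, x$threshold, 100 * x$fraction_inverted,
              100 * x$fraction_normal, length(x$labels)))
  invisible(x)
}

# ---- data-frame-first wrappers over the snapshot table ---------------------

#' Fit the three laws to a snapshot table
#'
#' Convenience wrappers taking the standard snapshot table (columns
#' `rc_nm`, `neg_sfeg_ev`, `ln_rate`): `fit_segl()` fits the energy gap law
#' (parabola of `ln_rate` on `neg_sfeg_ev`), `fit_exdl()` fits/classifies
#' the extended Dutton law (`ln_rate` on `rc_nm`), and `fit_esrc()` fits the
#' distance--energy line (`neg_sfeg_ev` on `rc_nm`).
#'
#' @param data A data frame with the columns named above.
#' @param ... Passed to [classify_relationship()] by `fit_exdl()`.
#' @return `fit_segl()` a `parabolic_fit`; `fit_exdl()` a `law_class`;
#'   `fit_esrc()` a `linear_fit`.
#' @export
fit_segl <- function(data) {
  need_cols(data, c("neg_sfeg_ev", "ln_rate"))
  fit_parabola(data$neg_sfeg_ev, data$ln_rate, law = "SEGL")
}

#' @rdname fit_segl
#' @export
fit_exdl <- function(data, ...) {
  need_cols(data, c("rc_nm", "ln_rate"))
  classify_relationship(data$rc_nm, data$ln_rate, ...)
}

#' @rdname fit_segl
#' @export
fit_esrc <- function(data) {
  need_cols(data, c("rc_nm", "neg_sfeg_ev"))
  fit_line(data$rc_nm, data$neg_sfeg_ev, law = "ESRC")
}

need_cols <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}
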