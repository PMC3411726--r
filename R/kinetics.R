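# Pseudo-first-order depletion of the unadducted peptide from SIM
# (selected ion monitoring) peak-area time courses.
#
# The source experiments report depletion qualitatively as percent of
# peptide remaining; the exponential-decay fit is this package's
# formalization, and the model-free fraction remaining at the last time
# point (f8 on the standard 8-minute grid) is always reported alongside.

.check_timecourse <- function(tc, arg = "tc") {
  stopifnot(is.data.frame(tc))
  need <- c("time_min", "area")
  missing <- setdiff(need, names(tc))
  if (length(missing) > 0) {
    abort(sprintf("%s lacks column(s): %s", arg, paste(missing, collapse = ", ")))
  }
  if (nrow(tc) < 3) abort(sprintf("%s needs at least 3 time points", arg))
  if (is.unsorted(tc$time_min, strictly = TRUE)) {
    abort(sprintf("%s times must be strictly increasing", arg))
  }
  if (tc$time_min[1] != 0) abort(sprintf("%s must start at time 0", arg))
  if (any(tc$area < 0)) abort(sprintf("%s areas must be non-negative", arg))
  if (tc$area[1] <= 0) abort(sprintf("%s area at time 0 must be positive", arg))
  invisible(tc)
}

#' Fraction of peptide remaining at a sampled time
#'
#' @param tc A time course: data frame with columns `time_min` (strictly
#'   increasing, starting at 0) and `area` (SIM peak area).
#' @param t A sampled time in minutes; no interpolation is performed.
#' @return `area(t) / area(0)`.
#' @export
fraction_remaining <- function(tc, t) {
  .check_timecourse(tc)
  i <- match(t, tc$time_min)
  if (anyNA(i)) {
    abort(sprintf("time %s was not sampled (no interpolation)",
                  paste(t[is.na(i)], collapse = ", ")))
  }
  tc$area[i] / tc$area[1]
}

#' Fit first-order depletion to a SIM time course
#'
#' Least-squares line through `(t, log(area / area0))`; the rate constant
#' is minus the slope, clamped at zero. If a metabolite-free `control`
#' course on the same time grid is supplied, areas are first divided
#' pointwise by the control's fraction remaining, removing instrument and
#' hydrolysis drift. Zero-area points are dropped from the log fit with a
#' warning; fewer than three positive points is an error.
#'
#' @inheritParams fraction_remaining
#' @param control Optional control time course on the same grid.
#' @return An object of class `"nap_depletion_fit"` with elements `k`
#'   (min^-1), `k_se`, `half_life` (min), `f_end` (model-free fraction
#'   remaining at the last time point, clamped to `[0, 1]`), `r_squared`,
#'   `n_points`, `data` and `model`.
#' @examples
#' tc <- tibble::tibble(time_min = c(0, 0.5, 1, 2, 4, 8),
#'                      area = 1e6 * exp(-0.2 * c(0, 0.5, 1, 2, 4, 8)))
#' fit_depletion(tc)
#' @export
fit_depletion <- function(tc, control = NULL) {
  .check_timecourse(tc)
  area <- tc$area
  if (!is.null(control)) {
    .check_timecourse(control, "control")
    if (!identical(as.numeric(control$time_min), as.numeric(tc$time_min))) {
      abort("control must share the signal's time grid")
    }
    area <- area / (control$area / control$area[1])
  }
  frac <- area / area[1]
  keep <- frac > 0
  if (any(!keep)) warn(sprintf("dropping %d zero-area point(s) from the log fit",
                               sum(!keep)))
  if (sum(keep) < 3) abort("fewer than 3 positive points; cannot fit")
  t <- tc$time_min[keep]
  y <- log(frac[keep])
  fit <- lm(y ~ t)
  slope <- unname(coef(fit)[2])
  # noiseless input is a legitimate case; lm warns about the perfect fit
  smry <- suppressWarnings(summary(fit))
  se <- smry$coefficients["t", "Std. Error"]
  r2 <- smry$r.squared
  k <- max(0, -slope)
  f_end <- min(1, max(0, frac[length(frac)]))
  structure(
    list(k = k, k_se = se, half_life = if (k > 0) log(2) / k else Inf,
         f_end = f_end, r_squared = r2, n_points = sum(keep),
         t_end = tc$time_min[nrow(tc)],
         data = tibble::tibble(time_min = tc$time_min, area = tc$area,
                               corrected = area, fraction = frac),
         model = fit),
    class = "nap_depletion_fit"
  )
}

#' @export
print.nap_depletion_fit <- function(x, ...) {
  cat(sprintf(
    "<depletion fit> k = %.4g min^-1 (se %.2g), t1/2 = %.3g min, f(%g min) = %.3f, r^2 = %.4f\n",
    x$k, x$k_se, x$half_life, x$t_end, x$f_end, x$r_squared))
  invisible(x)
}

#' @rdname fit_depletion
#' @param x A `"nap_depletion_fit"` object.
#' @param ... Unused.
#' @method tidy nap_depletion_fit
#' @export
tidy.nap_depletion_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "half_life", "f_end"),
    estimate = c(x$k, x$half_life, x$f_end),
    std.error = c(x$k_se, NA_real_, NA_real_)
  )
}

#' @rdname fit_depletion
#' @method glance nap_depletion_fit
#' @export
glance.nap_depletion_fit <- function(x, ...) {
  tibble::tibble(k = x$k, k_se = x$k_se, half_life = x$half_life,
                 f_end = x$f_end, r_squared = x$r_squared,
                 n_points = x$n_points)
}

#' @rdname fit_depletion
#' @param object A `"nap_depletion_fit"` object.
#' @method autoplot nap_depletion_fit
#' @export
autoplot.nap_depletion_fit <- function(object, ...) {
  d <- object$data
  curve <- tibble::tibble(
    time_min = seq(0, max(d$time_min), length.out = 100))
  curve$fraction <- exp(-object$k * curve$time_min)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min, y = .data$fraction)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curve, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (min)", y = "fraction of unadducted peptide",
                  title = sprintf("k = %.3g min^-1, t1/2 = %.3g min",
                                  object$k, object$half_life)) +
    ggplot2::theme_minimal()
}

#' Rank depletion time courses by fitted rate
#'
#' Fits each course and orders them by `k`, fastest first. Two successive
#' courses are declared distinguishable (`"faster"` than the next) only
#' when their approximate 95% intervals `k +/- 1.96 se` are disjoint;
#' otherwise `"similar"`.
#'
#' @param courses A data frame with columns `label`, `time_min`, `area`
#'   (one course per label), or a named list of time-course data frames.
#' @param control Optional shared control course for drift correction.
#' @return A tibble with one row per course: `label`, `k`, `k_se`,
#'   `ci_lo`, `ci_hi`, `half_life`, `f_end`, `r_squared`, `vs_next`.
#' @export
compare_depletion <- function(courses, control = NULL) {
  if (is.data.frame(courses)) {
    if (!"label" %in% names(courses)) {
      abort("long-format courses need a 'label' column")
    }
    courses <- split(courses[c("time_min", "area")], courses$label)
  }
  if (length(courses) < 2) abort("need at least two courses to compare")
  grids <- lapply(courses, function(tc) as.numeric(tc$time_min))
  if (!all(vapply(grids, identical, logical(1), grids[[1]]))) {
    abort("courses must share a common time grid")
  }
  fits <- lapply(courses, fit_depletion, control = control)
  out <- dplyr::bind_rows(lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    tibble::tibble(label = nm, k = f$k, k_se = f$k_se,
                   ci_lo = f$k - 1.96 * f$k_se, ci_hi = f$k + 1.96 * f$k_se,
                   half_life = f$half_life, f_end = f$f_end,
                   r_squared = f$r_squared)
  }))
  out <- out[order(-out$k), , drop = FALSE]
  n <- nrow(out)
  out$vs_next <- c(vapply(seq_len(n - 1), function(i) {
    if (out$ci_lo[i] > out$ci_hi[i + 1]) "faster" else "similar"
  }, character(1)), NA_character_)
  out
}
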