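#' Map a posture covariate to anteroposterior center of support
#'
#' Least-squares linear fit of standstill \code{CoS_AP_cm} against a
#' covariate (snout-hump angle or surface slope) with per-mouse intercepts
#' (lme4 random intercepts when at least three mice are available, plain
#' least squares otherwise). The fitted covariate range is stored and
#' monotonicity (a non-zero slope) is asserted.
#'
#' @param load_summaries data.frame of [summarize_load_trial()] rows (or any
#'   table with \code{CoS_AP_cm}, \code{mouse_id} and the covariate column).
#' @param covariate covariate column name (e.g. \code{"snout_hump_angle"},
#'   \code{"slope"}).
#' @param min_levels minimum number of distinct covariate levels (default 4).
#' @return list of class \code{"cos_map"}: \code{slope} (cm per covariate
#'   unit), \code{intercept}, \code{covariate}, \code{covariate_range},
#'   \code{cos_range}, \code{per_mouse} (intercept offsets), \code{n}.
#' @export
build_cos_map <- function(load_summaries, covariate, min_levels = 4) {
  df <- as.data.frame(load_summaries)
  stopifnot(all(c("CoS_AP_cm", covariate) %in% names(df)))
  x <- df[[covariate]]
  if (length(unique(x)) < min_levels)
    stop("need at least ", min_levels, " distinct covariate levels")
  y <- df$CoS_AP_cm
  g <- factor(df$mouse_id %||% rep("m1", nrow(df)))
  if (nlevels(g) >= 3) {
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(y ~ x + (1 | g),
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    fe <- lme4::fixef(fit)
    slope <- unname(fe["x"]); intercept <- unname(fe["(Intercept)"])
    per_mouse <- setNames(lme4::ranef(fit)$g[, 1], rownames(lme4::ranef(fit)$g))
  } else {
    fit <- lm(y ~ x)
    slope <- unname(coef(fit)["x"]); intercept <- unname(coef(fit)["(Intercept)"])
    per_mouse <- setNames(rep(0, nlevels(g)), levels(g))
  }
  if (abs(slope) < 1e-10)
    warning("fitted CoS map is flat; mapping is not invertible")
  structure(list(
    slope = slope, intercept = intercept, covariate = covariate,
    covariate_range = range(x),
    cos_range = sort(intercept + slope * range(x)),
    per_mouse = per_mouse, n = nrow(df)
  ), class = "cos_map")
}

#' @exportS3Method base::print
print.cos_map <- function(x, ...) {
  cat(sprintf("<cos_map: CoS_AP_cm = %.4f %+.4f * %s, %s in [%.1f, %.1f]>\n",
              x$intercept, x$slope, x$covariate, x$covariate,
              x$covariate_range[1], x$covariate_range[2]))
  invisible(x)
}

#' Invert a CoS map
#'
#' @param map a [build_cos_map()] result.
#' @param cos_ap CoS values (cm) to map back to the covariate scale.
#' @param extrapolate allow values outside the fitted CoS range? When
#'   \code{FALSE} (default) out-of-range requests are flagged with a
#'   warning and returned as \code{NA}.
#' @return covariate values.
#' @export
cos_to_covariate <- function(map, cos_ap, extrapolate = FALSE) {
  out <- (cos_ap - map$intercept) / map$slope
  outside <- cos_ap < map$cos_range[1] - 1e-9 | cos_ap > map$cos_range[2] + 1e-9
  if (any(outside) && !extrapolate) {
    warning("extrapolation outside the fitted CoS range flagged as NA")
    out[outside] <- NA_real_
  }
  out
}

#' Phase shift as a function of center-of-support position
#'
#' Composes a circular-linear phase regression with a covariate-to-CoS map,
#' expressing the fitted population mean phase as a function of
#' anteroposterior CoS over \code{cos_range}, relative to the most
#' fore-loaded (largest CoS) end of that range. When the regression carries
#' bootstrap draws, a resampling interval for the shift across the whole
#' range is attached.
#'
#' @param fit a \code{"circ_reg"} whose design includes the map's covariate.
#' @param cos_map a [build_cos_map()] for the same covariate.
#' @param cos_range length-2 numeric, CoS interval (cm) to evaluate; must
#'   lie inside the map's fitted range.
#' @param n_grid grid resolution.
#' @param conf_level interval level for the bootstrap band.
#' @return list of class \code{"cos_phase_curve"}: \code{cos_grid},
#'   \code{phase} (rad, population mean), \code{phase_shift} (rad, relative
#'   to the fore-loaded end), \code{shift_over_range} (rad),
#'   \code{rad_per_cm}, \code{shift_ci} (bootstrap interval or NULL),
#'   \code{covariate}.
#' @export
phase_shift_per_cos <- function(fit, cos_map, cos_range, n_grid = 50,
                                conf_level = 0.95) {
  cov <- cos_map$covariate
  if (!(cov %in% names(fit$beta)))
    stop("regression fit has no coefficient for map covariate '", cov, "'")
  if (cos_range[1] < cos_map$cos_range[1] - 1e-9 ||
      cos_range[2] > cos_map$cos_range[2] + 1e-9)
    stop("requested CoS range lies outside the fitted map validity")
  grid <- seq(min(cos_range), max(cos_range), length.out = n_grid)
  xg <- cos_to_covariate(cos_map, grid)
  nd <- as.data.frame(setNames(lapply(names(fit$beta), function(nm)
    if (nm == cov) xg else rep(fit$centers[[nm]], n_grid)), names(fit$beta)))
  mu <- predict(fit, nd)
  ref <- which.max(grid) # most fore-loaded extreme (largest CoS_AP)
  shift <- wrap_pi(mu - mu[ref])
  shift_range <- shift[which.min(grid)]

  shift_ci <- NULL
  if (!is.null(fit$boot)) {
    b <- fit$boot[, cov]
    b <- b[!is.na(b)]
    ctr <- fit$centers[[cov]]
    x_lo <- xg[which.min(grid)]; x_hi <- xg[which.max(grid)]
    draws <- 2 * (atan(b * (x_lo - ctr)) - atan(b * (x_hi - ctr)))
    a <- (1 - conf_level) / 2
    shift_ci <- quantile(draws, c(a, 1 - a), names = FALSE)
  }
  structure(list(
    cos_grid = grid, phase = mu, phase_shift = shift,
    shift_over_range = shift_range,
    rad_per_cm = shift_range / (min(grid) - max(grid)),
    shift_ci = shift_ci, covariate = cov
  ), class = "cos_phase_curve")
}

#' @exportS3Method base::print
print.cos_phase_curve <- function(x, ...) {
  cat(sprintf(
    "<cos_phase_curve (%s): shift over [%.2f, %.2f] cm = %+.3f rad (%.2f pi)>\n",
    x$covariate, min(x$cos_grid), max(x$cos_grid),
    x$shift_over_range, x$shift_over_range / pi))
  if (!is.null(x$shift_ci))
    cat(sprintf("  bootstrap interval: [%.3f, %.3f] rad\n",
                x$shift_ci[1], x$shift_ci[2]))
  invisible(x)
}

#' Agreement between two composed phase-vs-CoS curves
#'
#' Compares two [phase_shift_per_cos()] curves (e.g. head-height and slope
#' trial types) on their common CoS support: maximal and mean absolute
#' circular difference of the phase-shift curves, and — when both carry
#' bootstrap intervals — whether the whole-range shift intervals overlap.
#'
#' @param curve_a,curve_b \code{"cos_phase_curve"} objects.
#' @return list with \code{max_abs_diff}, \code{mean_abs_diff} (rad),
#'   \code{intervals_overlap} (logical or NA).
#' @export
cos_curve_agreement <- function(curve_a, curve_b) {
  lo <- max(min(curve_a$cos_grid), min(curve_b$cos_grid))
  hi <- min(max(curve_a$cos_grid), max(curve_b$cos_grid))
  if (hi <= lo) stop("curves share no CoS support")
  g <- seq(lo, hi, length.out = 50)
  sa <- approx(curve_a$cos_grid, curve_a$phase_shift, xout = g)$y
  sb <- approx(curve_b$cos_grid, curve_b$phase_shift, xout = g)$y
  d <- abs(wrap_pi(sa - sb))
  overlap <- if (!is.null(curve_a$shift_ci) && !is.null(curve_b$shift_ci)) {
    curve_a$shift_ci[1] <= curve_b$shift_ci[2] &&
      curve_b$shift_ci[1] <= curve_a$shift_ci[2]
  } else NA
  list(max_abs_diff = max(d), mean_abs_diff = mean(d),
       intervals_overlap = overlap)
}
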