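#' Standstill detection and per-limb weight fractions
#'
#' Finds the longest contiguous run of low-variance total load (rolling 1 s
#' windows with total-load coefficient of variation below \code{cv_max});
#' the trial qualifies only if that run lasts at least \code{standstill_min}
#' seconds. Fractions are the per-channel means over the window divided by
#' their sum.
#'
#' @param trial a \code{"load_trial"} (see [generate_load_trial()],
#'   [read_load_csv()]); metadata must carry \code{sample_rate}.
#' @param standstill_min minimum standstill duration (s), default 5.
#' @param cv_max maximal coefficient of variation of total load within a
#'   rolling 1 s window.
#' @return list with \code{fractions} (named RF, LF, RH, LH, summing to 1),
#'   \code{window} (frame range used), \code{mean_total} (g).
#'   Errors with a reason when no qualifying window exists.
#' @export
weight_fractions <- function(trial, standstill_min = 5, cv_max = 0.05) {
  sr <- trial$metadata$sample_rate
  if (is.null(sr)) stop("trial metadata must include sample_rate")
  total <- rowSums(trial$forces)
  w <- max(2L, as.integer(round(sr)))
  n <- length(total)
  if (n < w) stop("trial rejected: shorter than one rolling window")
  mu <- as.numeric(stats::filter(total, rep(1 / w, w), sides = 1))
  mu2 <- as.numeric(stats::filter(total^2, rep(1 / w, w), sides = 1))
  sdv <- sqrt(pmax(mu2 - mu^2, 0))
  still <- !is.na(mu) & sdv / pmax(abs(mu), 1e-12) < cv_max
  r <- rle(still)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) stop("trial rejected: no standstill window found")
  best <- runs[which.max(r$lengths[runs])]
  # rolling stats are right-aligned: the run covers samples back to start - w + 1
  lo <- max(1L, starts[best] - w + 1L); hi <- ends[best]
  if ((hi - lo + 1) / sr < standstill_min)
    stop(sprintf("trial rejected: longest standstill %.2f s < %.2f s",
                 (hi - lo + 1) / sr, standstill_min))
  m <- colMeans(trial$forces[lo:hi, , drop = FALSE])
  list(fractions = m / sum(m), window = c(lo, hi), mean_total = sum(m))
}

#' Center-of-support indices from weight fractions
#'
#' Anteroposterior: \code{w_RF + w_LF - (w_RH + w_LH)} (positive =
#' fore-biased). Mediolateral: \code{w_RF + w_RH - (w_LF + w_LH)}.
#'
#' @param w named fractions (RF, LF, RH, LH) summing to 1.
#' @return named vector \code{c(CoS_AP_index, CoS_ML_index)}, each in
#'   \code{[-1, 1]}.
#' @export
center_of_support_index <- function(w) {
  stopifnot(all(c("RF", "LF", "RH", "LH") %in% names(w)))
  c(CoS_AP_index = unname(w[["RF"]] + w[["LF"]] - (w[["RH"]] + w[["LH"]])),
    CoS_ML_index = unname(w[["RF"]] + w[["RH"]] - (w[["LF"]] + w[["LH"]])))
}

#' Load-weighted center-of-support position
#'
#' \code{sum(w_i * position_i)} per axis, in cm.
#'
#' @param w named fractions (RF, LF, RH, LH).
#' @param foot_positions data.frame with columns \code{foot}, \code{ap_cm},
#'   \code{ml_cm} covering all four feet.
#' @return named vector \code{c(CoS_AP_cm, CoS_ML_cm)}.
#' @export
center_of_support_position <- function(w, foot_positions) {
  need <- c("RF", "LF", "RH", "LH")
  if (!all(need %in% foot_positions$foot))
    stop("missing foot position(s): ",
         paste(setdiff(need, foot_positions$foot), collapse = ", "))
  fp <- foot_positions[match(need, foot_positions$foot), ]
  ww <- unlist(w[need])
  c(CoS_AP_cm = sum(ww * fp$ap_cm), CoS_ML_cm = sum(ww * fp$ml_cm))
}

#' Detectable weight on a sloped surface
#'
#' Only the vertical force component is recorded, so the detectable body
#' weight reduces to \code{cos(slope) * weight}.
#'
#' @param weight body weight (g).
#' @param slope surface slope (deg), \code{|slope| < 90}.
#' @return detectable weight (g).
#' @export
slope_detectable_weight <- function(weight, slope) {
  if (abs(slope) >= 90) stop("|slope| must be < 90 degrees")
  cos(slope * pi / 180) * weight
}

#' Maximum comfortable head height
#'
#' Empirical linear relation between body weight and the highest head
#' fixation at which both forefeet remain grounded:
#' \code{24.5 + 1.25 * weight}.
#'
#' @param weight body weight (g), non-negative (0 returns the intercept).
#' @return height in mm.
#' @export
max_comfortable_height <- function(weight) {
  stopifnot(all(weight >= 0))
  24.5 + 1.25 * weight
}

#' Weight-adjusted head height
#'
#' \code{(physical_height - 24.5) / (1.25 * weight)}; equals 1 at the
#' maximum comfortable head height for that weight.
#'
#' @param physical_height head height (mm).
#' @param weight body weight (g), \code{> 0}.
#' @return dimensionless height.
#' @export
weight_adjusted_head_height <- function(physical_height, weight) {
  stopifnot(all(weight > 0))
  (physical_height - 24.5) / (1.25 * weight)
}

#' Fit an exponential decay / saturation curve
#'
#' Nonlinear least squares for \code{y = A - B * exp(-k * x)} with empirical
#' initialization: \code{A} from the observed maximum, \code{B} from the
#' difference between the initial \code{y} and \code{A}, and \code{k} as the
#' inverse of the mean predictor value.
#'
#' @param x,y numeric vectors, \code{length >= 4}, finite \code{x}.
#' @param subject optional grouping; when given, the curve is also fit per
#'   subject.
#' @return list of class \code{"exp_decay_fit"}: \code{A}, \code{B},
#'   \code{k}, \code{converged}, \code{fitted}, and (when grouped)
#'   \code{per_subject} data.frame.
#' @export
fit_exponential_decay <- function(x, y, subject = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 4, all(is.finite(x)))
  fit1 <- function(x, y) {
    A0 <- max(y)
    B0 <- A0 - y[which.min(x)]
    k0 <- 1 / mean(x)
    out <- list(A = NA_real_, B = NA_real_, k = NA_real_, converged = FALSE)
    # near-constant response: k unidentifiable
    if (sd(y) < 1e-10 * max(abs(y), 1)) {
      out$A <- mean(y); out$B <- 0
      return(out)
    }
    ft <- tryCatch(
      minpack.lm::nlsLM(y ~ A - B * exp(-k * x),
                        start = list(A = A0, B = B0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(ft)) return(out)
    cf <- coef(ft)
    list(A = unname(cf["A"]), B = unname(cf["B"]), k = unname(cf["k"]),
         converged = TRUE)
  }
  res <- fit1(x, y)
  res$fitted <- if (res$converged) res$A - res$B * exp(-res$k * x) else rep(NA_real_, length(x))
  if (!is.null(subject)) {
    per <- lapply(split(data.frame(x, y), subject), function(d) {
      if (nrow(d) >= 4) fit1(d$x, d$y) else list(A = NA, B = NA, k = NA, converged = FALSE)
    })
    res$per_subject <- data.frame(
      subject = names(per),
      A = vapply(per, function(p) p$A, numeric(1)),
      B = vapply(per, function(p) p$B, numeric(1)),
      k = vapply(per, function(p) p$k, numeric(1)),
      converged = vapply(per, function(p) isTRUE(p$converged), logical(1))
    )
  }
  class(res) <- "exp_decay_fit"
  res
}

#' Summarize a standstill load trial
#'
#' Combines [weight_fractions()], the center-of-support formulas, the slope
#' correction and the head-post offload into one record.
#'
#' @param trial a \code{"load_trial"}; metadata must carry \code{weight},
#'   \code{slope}, \code{head_height}, \code{sample_rate} and (for cm-valued
#'   CoS) \code{foot_positions}.
#' @param standstill_min minimum standstill duration (s).
#' @param cv_max rolling-window CV threshold for standstill detection.
#' @return one-row data.frame of class \code{"load_summary"}: weight
#'   fractions, CoS indices and (when geometry is available) cm positions,
#'   detected fraction, offload fraction, weight-adjusted head height.
#' @export
summarize_load_trial <- function(trial, standstill_min = 5, cv_max = 0.05) {
  md <- trial$metadata
  wf <- weight_fractions(trial, standstill_min = standstill_min, cv_max = cv_max)
  w <- wf$fractions
  idx <- center_of_support_index(w)
  pos <- if (!is.null(md$foot_positions)) {
    center_of_support_position(as.list(w), md$foot_positions)
  } else c(CoS_AP_cm = NA_real_, CoS_ML_cm = NA_real_)
  detectable <- slope_detectable_weight(md$weight, md$slope %||% 0)
  detected_fraction <- wf$mean_total / detectable
  out <- data.frame(
    mouse_id = md$mouse_id %||% NA_character_,
    weight = md$weight, head_height = md$head_height %||% NA_real_,
    slope = md$slope %||% 0,
    snout_hump_angle = md$snout_hump_angle %||% NA_real_,
    w_RF = w[["RF"]], w_LF = w[["LF"]], w_RH = w[["RH"]], w_LH = w[["LH"]],
    CoS_AP_index = idx[["CoS_AP_index"]], CoS_ML_index = idx[["CoS_ML_index"]],
    CoS_AP_cm = pos[["CoS_AP_cm"]], CoS_ML_cm = pos[["CoS_ML_cm"]],
    detected_fraction = detected_fraction,
    offload_fraction = 1 - detected_fraction,
    weight_adjusted_head_height =
      if (!is.null(md$head_height)) weight_adjusted_head_height(md$head_height, md$weight)
      else NA_real_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("load_summary", class(out))
  out
}
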