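#' Construct a trajectory recording
#'
#' Container for per-trial multi-bodypart pose series with tracking
#' likelihoods, a frame rate, an optional belt-speed channel and trial
#' metadata. All series must share the same length and likelihoods must lie
#' in \code{[0, 1]}.
#'
#' @param x,y,likelihood numeric matrices (frames x bodyparts) with matching
#'   column names.
#' @param frame_rate frames per second, \code{> 0}.
#' @param belt_speed optional belt-speed series (cm/s).
#' @param metadata list of trial metadata (mouse_id, weight, head_height,
#'   slope, stim_freq, stim_side, ...).
#' @return object of class \code{"trajectory_recording"}.
#' @export
trajectory_recording <- function(x, y, likelihood, frame_rate,
                                 belt_speed = NULL, metadata = list()) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  stopifnot(
    nrow(x) == nrow(y), nrow(x) == nrow(likelihood),
    identical(colnames(x), colnames(y)),
    identical(colnames(x), colnames(likelihood)),
    frame_rate > 0,
    all(likelihood >= 0 & likelihood <= 1)
  )
  if (!is.null(belt_speed)) stopifnot(length(belt_speed) == nrow(x))
  structure(list(
    x = x, y = y, likelihood = likelihood,
    frames = nrow(x), frame_rate = frame_rate,
    belt_speed = belt_speed, metadata = metadata
  ), class = "trajectory_recording")
}

#' @exportS3Method base::print
print.trajectory_recording <- function(x, ...) {
  cat(sprintf("<trajectory_recording: %d frames @ %g Hz, %d bodyparts>\n",
              x$frames, x$frame_rate, ncol(x$x)))
  cat("bodyparts:", paste(colnames(x$x), collapse = ", "), "\n")
  invisible(x)
}

#' Likelihood-based trial inclusion and cleaning
#'
#' A trial is included when at least \code{snout_hump_min_frac} of snout and
#' hump frames, and at least \code{ref_limb_min_frac} of reference-limb
#' frames, have tracking likelihood \code{>= likelihood_min}. Sub-threshold
#' frames of every bodypart are linearly interpolated and flagged.
#'
#' @param rec a [trajectory_recording()].
#' @param likelihood_min likelihood threshold (default 0.95).
#' @param snout_hump_min_frac required fraction of confident snout/hump frames.
#' @param ref_limb_min_frac required fraction of confident reference-limb frames.
#' @param reference_limb foot id whose landmarks form the reference
#'   (\code{"LH"}: left hindlimb).
#' @return list with \code{included} (logical), \code{fractions} (named
#'   confident-frame fractions), \code{recording} (cleaned copy) and
#'   \code{interpolated} (logical matrix of replaced frames).
#' @export
filter_tracking <- function(rec, likelihood_min = 0.95,
                            snout_hump_min_frac = 0.90,
                            ref_limb_min_frac = 0.80,
                            reference_limb = "LH") {
  bp <- colnames(rec$x)
  ref_parts <- grep(paste0("^", reference_limb), bp, value = TRUE)
  required <- c("snout", "hump", ref_parts)
  missing <- setdiff(c("snout", "hump"), bp)
  if (length(ref_parts) == 0) missing <- c(missing, reference_limb)
  if (length(missing) > 0)
    stop("missing required bodypart(s): ", paste(missing, collapse = ", "))

  frac <- colMeans(rec$likelihood >= likelihood_min)
  included <- all(frac[c("snout", "hump")] >= snout_hump_min_frac) &&
    all(frac[ref_parts] >= ref_limb_min_frac)

  low <- rec$likelihood < likelihood_min
  cleaned <- rec
  for (j in seq_along(bp)) {
    idx <- which(low[, j])
    if (length(idx) == 0 || length(idx) == rec$frames) next
    keep <- which(!low[, j])
    cleaned$x[idx, j] <- approx(keep, rec$x[keep, j], xout = idx, rule = 2)$y
    cleaned$y[idx, j] <- approx(keep, rec$y[keep, j], xout = idx, rule = 2)$y
  }
  list(included = included, fractions = frac,
       recording = cleaned, interpolated = low)
}

#' Snout-hump posture angle
#'
#' The obtuse angle between the hump-to-snout vector and a surface-parallel
#' line through the snout: \code{180 - |elevation|} degrees, where the
#' elevation is measured in surface-parallel coordinates (forward along
#' \code{-x} under the left side-view image convention). Invariant to rigid
#' rotation of the scene together with the surface, and to uniform scaling.
#'
#' @param snout_xy,hump_xy length-2 vectors or 2-column matrices (mm);
#'   columns x (rearward-positive), y (up).
#' @param slope surface slope (deg) when coordinates are in the lab frame;
#'   0 when coordinates are already surface-parallel.
#' @return angle(s) in degrees, in (90, 180].
#' @export
snout_hump_angle <- function(snout_xy, hump_xy, slope = 0) {
  s <- rbind(snout_xy); h <- rbind(hump_xy)
  dx <- s[, 1] - h[, 1]; dy <- s[, 2] - h[, 2]
  if (any(abs(dx) < 1e-12 & abs(dy) < 1e-12))
    stop("degenerate geometry: snout and hump coincide")
  # forward = -x: elevation of hump->snout vector above surface-parallel
  elev <- atan2(dy, -dx) * 180 / pi - slope
  as.numeric(180 - abs(wrap_pi(elev * pi / 180)) * 180 / pi)
}

#' Locomotion mask from belt speed
#'
#' @param belt_speed speed series (cm/s); must be finite.
#' @param threshold locomotion threshold (cm/s), default 1.
#' @return logical vector; contiguous \code{TRUE} runs are locomotor bouts.
#' @export
locomotion_mask <- function(belt_speed, threshold = 1) {
  if (!all(is.finite(belt_speed))) stop("belt_speed must be finite")
  belt_speed > threshold
}

#' Locomotor bouts from a mask
#'
#' @param mask logical vector from [locomotion_mask()].
#' @param min_frames minimum bout length in frames.
#' @return data.frame with \code{start}, \code{end} (inclusive frame indices)
#'   and \code{length}.
#' @export
locomotor_bouts <- function(mask, min_frames = 1L) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Posture and speed series for a trial
#'
#' Computes the per-frame snout-hump angle, the locomotor speed (belt channel
#' when present, otherwise the median rearward foot velocity during stance)
#' and the locomotion mask.
#'
#' @param rec a [trajectory_recording()] (ideally cleaned by
#'   [filter_tracking()]).
#' @param speed_threshold locomotion threshold (cm/s).
#' @param slope surface slope (deg) used for the angle when the coordinates
#'   are lab-frame; generated recordings are surface-parallel (slope = 0).
#' @return data.frame of class \code{"posture_series"}: \code{frame},
#'   \code{snout_hump_angle} (deg), \code{speed} (cm/s), \code{locomoting}.
#' @export
posture_series <- function(rec, speed_threshold = 1, slope = 0) {
  ang <- snout_hump_angle(cbind(rec$x[, "snout"], rec$y[, "snout"]),
                          cbind(rec$x[, "hump"], rec$y[, "hump"]),
                          slope = slope)
  if (!is.null(rec$belt_speed)) {
    spd <- rec$belt_speed
  } else {
    feet <- grep("^(LF|RF|LH|RH)", colnames(rec$x), value = TRUE)
    # rearward drift (dx > 0) during stance, mm/frame -> cm/s
    v <- apply(rec$x[, feet, drop = FALSE], 2, function(z) c(diff(z), NA))
    v[v <= 0] <- NA
    spd <- apply(v, 1, median, na.rm = TRUE) * rec$frame_rate / 10
    spd[!is.finite(spd)] <- 0
  }
  out <- data.frame(
    frame = seq_len(rec$frames),
    snout_hump_angle = ang,
    speed = spd,
    locomoting = locomotion_mask(spd, speed_threshold)
  )
  class(out) <- c("posture_series", "data.frame")
  out
}
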