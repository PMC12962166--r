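#' Segment a limb trajectory into strides
#'
#' Peak detection on the horizontal foot coordinate (image convention:
#' increases rearward, so values rise slowly during stance and fall rapidly
#' during swing). Peaks mark swing onsets, troughs mark stance onsets, and
#' strides are the half-open intervals between consecutive swing onsets; the
#' trailing partial stride is truncated at the final swing onset.
#'
#' Detection defaults are scale-free: the minimum inter-peak period is half
#' the dominant period found by autocorrelation and the minimum prominence is
#' 20\% of the trajectory range.
#'
#' @param limb_x horizontal foot coordinate (mm), one locomotor bout.
#' @param frame_rate frames per second.
#' @param min_period minimum stride period (s); \code{NULL} for the
#'   autocorrelation default.
#' @param min_prominence minimum peak prominence (mm); \code{NULL} for 20\%
#'   of the range.
#' @return list of class \code{"stride_segmentation"}: \code{swing_onsets},
#'   \code{stance_onsets} (frame indices), \code{strides} (data.frame with
#'   \code{onset}, \code{offset}), \code{n_strides}.
#' @export
segment_strides <- function(limb_x, frame_rate, min_period = NULL,
                            min_prominence = NULL) {
  n <- length(limb_x)
  empty <- structure(list(swing_onsets = integer(0), stance_onsets = integer(0),
                          strides = data.frame(onset = integer(0), offset = integer(0)),
                          n_strides = 0L),
                     class = "stride_segmentation")
  rng <- diff(range(limb_x))
  if (n < 4 || rng < .Machine$double.eps^0.5) return(empty)
  if (is.null(min_prominence)) min_prominence <- 0.2 * rng
  if (is.null(min_period)) {
    xc <- limb_x - mean(limb_x)
    ac <- stats::acf(xc, lag.max = min(n - 1, 5 * frame_rate), plot = FALSE)$acf[, 1, 1]
    pk <- pracma::findpeaks(ac, minpeakheight = 0.2)
    min_period <- if (!is.null(pk)) 0.5 * (pk[1, 2] - 1) / frame_rate else 4 / frame_rate
  }
  mpd <- max(2L, as.integer(round(min_period * frame_rate)))
  pk <- pracma::findpeaks(as.numeric(limb_x), minpeakdistance = mpd)
  if (is.null(pk) || nrow(pk) < 1) return(empty)
  peaks <- sort(pk[, 2])
  # simple prominence: drop to the lower of the two adjacent inter-peak minima
  keep <- vapply(seq_along(peaks), function(i) {
    lo <- if (i == 1) 1L else peaks[i - 1]
    hi <- if (i == length(peaks)) n else peaks[i + 1]
    prom <- limb_x[peaks[i]] - max(min(limb_x[lo:peaks[i]]), min(limb_x[peaks[i]:hi]))
    prom >= min_prominence
  }, logical(1))
  peaks <- peaks[keep]
  if (length(peaks) < 2) {
    if (length(peaks) < 1) return(empty)
    return(structure(list(swing_onsets = as.integer(peaks),
                          stance_onsets = integer(0),
                          strides = data.frame(onset = integer(0), offset = integer(0)),
                          n_strides = 0L), class = "stride_segmentation"))
  }
  troughs <- vapply(seq_len(length(peaks) - 1), function(i) {
    seg <- peaks[i]:peaks[i + 1]
    seg[which.min(limb_x[seg])]
  }, integer(1))
  structure(list(
    swing_onsets = as.integer(peaks),
    stance_onsets = as.integer(troughs),
    strides = data.frame(onset = peaks[-length(peaks)], offset = peaks[-1]),
    n_strides = length(peaks) - 1L
  ), class = "stride_segmentation")
}

#' @exportS3Method base::print
print.stride_segmentation <- function(x, ...) {
  cat(sprintf("<stride_segmentation: %d strides, %d swing onsets>\n",
              x$n_strides, length(x$swing_onsets)))
  invisible(x)
}

#' Interlimb phase of one stride by cross-correlation
#'
#' Mean-subtracted cross-correlation of the non-reference trajectory against
#' the reference over integer delays in \code{[-d/2, d/2]} for a stride of
#' duration \code{d} frames; the argmax lag, normalized by stride duration,
#' gives the phase \code{2 * pi * lag / d}, wrapped to \code{[-pi, pi)}.
#' Positive phase means the other limb's trajectory matches the reference
#' delayed (the other limb lags the reference). Ties break toward the
#' smaller \code{|lag|}; series are padded by their edge values where the
#' lagged window leaves the bout.
#'
#' @param ref_x,other_x horizontal trajectories (mm) on a common frame base.
#' @param onset,offset stride interval \code{[onset, offset)}, frame indices.
#' @param mean_subtract subtract window means before correlating
#'   (default TRUE).
#' @return phase in radians, or \code{NA} (undefined-phase flag) when either
#'   window has zero variance.
#' @export
relative_phase <- function(ref_x, other_x, onset, offset, mean_subtract = TRUE) {
  d <- offset - onset
  if (d < 2) return(NA_real_)
  idx <- onset:(offset - 1)
  half <- floor(d / 2)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  rw <- ref_x[idx]
  if (var(rw) < .Machine$double.eps) return(NA_real_)
  if (mean_subtract) rw <- rw - mean(rw)
  lags <- (-half):half
  cc <- vapply(lags, function(L) {
    ow <- other_x[clamp(idx + L, length(other_x))]
    if (var(ow) < .Machine$double.eps) return(NA_real_)
    if (mean_subtract) ow <- ow - mean(ow)
    sum(rw * ow)
  }, numeric(1))
  if (all(is.na(cc))) return(NA_real_)
  best <- max(cc, na.rm = TRUE)
  cand <- which(cc >= best - 1e-9 * abs(best) - 1e-12)
  lag <- lags[cand[which.min(abs(lags[cand]))]]
  wrap_pi(2 * pi * lag / d)
}

#' Dual-landmark phase consistency filter
#'
#' Keeps a stride only when the phases obtained from the two independently
#' tracked landmarks of the same foot agree to within \code{tol} on the
#' circle (default 0.1 pi rad).
#'
#' @param phase_a,phase_b phases (rad) from the two landmarks.
#' @param tol circular tolerance (rad).
#' @return logical: \code{TRUE} = keep. \code{NA} phases yield \code{FALSE}.
#' @export
consistency_filter <- function(phase_a, phase_b, tol = 0.1 * pi) {
  ok <- !is.na(phase_a) & !is.na(phase_b)
  out <- rep(FALSE, length(ok))
  out[ok] <- circ_dist(phase_a[ok], phase_b[ok]) <= tol
  out
}

#' Duty factor of a stride
#'
#' Fraction of the stride spent in stance: frames from the stance onset
#' inside the stride to the next swing onset, over the stride duration.
#'
#' @param segmentation a [segment_strides()] result.
#' @param onset,offset stride interval \code{[onset, offset)}.
#' @return duty factor in (0, 1), or \code{NA} when no stance onset falls
#'   inside the stride (flagged missing).
#' @export
duty_factor <- function(segmentation, onset, offset) {
  so <- segmentation$stance_onsets
  inside <- so[so > onset & so < offset]
  if (length(inside) == 0) return(NA_real_)
  (offset - inside[1]) / (offset - onset)
}

#' Categorize a hindlimb (left-right) phase
#'
#' Bands: alternating (\code{|phase| >= 0.8 pi}), synchronized
#' (\code{|phase| <= 0.2 pi}), otherwise asymmetric with the leading side
#' taken from the sign (positive phase = the non-reference limb lags the
#' reference left hindlimb, i.e. left-leading).
#'
#' @param phase phase(s) in radians (any representative; wrapped internally).
#' @return character vector over \{alternating, synchronized,
#'   asymmetric_left_leading, asymmetric_right_leading\}.
#' @export
categorize_hindlimb_phase <- function(phase) {
  p <- wrap_pi(phase)
  out <- ifelse(abs(p) >= 0.8 * pi, "alternating",
         ifelse(abs(p) <= 0.2 * pi, "synchronized",
         ifelse(p > 0, "asymmetric_left_leading", "asymmetric_right_leading")))
  out[is.na(phase)] <- NA_character_
  out
}

# mean foot trajectory over its two landmarks
.foot_mean_x <- function(rec, foot) {
  cols <- grep(paste0("^", foot, "[0-9]$"), colnames(rec$x), value = TRUE)
  rowMeans(rec$x[, cols, drop = FALSE])
}

#' Build the per-stride table for a trial
#'
#' Runs stride segmentation on the reference limb within each locomotor bout
#' and assembles, per stride: interlimb phases for every non-reference limb
#' (computed per tracked landmark, passed through the dual-landmark
#' consistency filter, then circularly averaged), per-limb duty factors and
#' the hind/fore duty-factor ratio, stride duration, mean speed, stride
#' length, mean snout-hump angle, and the hindlimb phase category. Strides
#' failing any filter are absent from the table; drop counts are attached as
#' the \code{"drop_log"} attribute.
#'
#' @param rec a cleaned [trajectory_recording()] (see [filter_tracking()]).
#' @param posture a [posture_series()] for the same trial.
#' @param reference_limb reference foot id (default \code{"LH"}).
#' @param tol dual-landmark consistency tolerance (rad), default 0.1 pi.
#' @param min_period,min_prominence passed to [segment_strides()].
#' @param trial_id identifier copied into the table.
#' @param mean_subtract passed to [relative_phase()].
#' @return data.frame of class \code{"stride_table"}, one row per kept
#'   stride of the reference limb.
#' @export
build_stride_table <- function(rec, posture, reference_limb = "LH",
                               tol = 0.1 * pi, min_period = NULL,
                               min_prominence = NULL, trial_id = "trial1",
                               mean_subtract = TRUE) {
  feet <- c("LF", "RF", "LH", "RH")
  others <- setdiff(feet, reference_limb)
  bouts <- locomotor_bouts(posture$locomoting,
                           min_frames = max(4L, as.integer(round(0.1 * rec$frame_rate))))
  drop_log <- c(consistency = 0L, undefined = 0L)
  rows <- list()
  lm_cols <- function(foot) grep(paste0("^", foot, "[0-9]$"), colnames(rec$x), value = TRUE)

  for (b in seq_len(nrow(bouts))) {
    fr <- bouts$start[b]:bouts$end[b]
    segs <- lapply(setNames(feet, feet), function(f)
      segment_strides(.foot_mean_x(rec, f)[fr], rec$frame_rate,
                      min_period = min_period, min_prominence = min_prominence))
    ref_seg <- segs[[reference_limb]]
    if (ref_seg$n_strides < 1) next
    for (i in seq_len(ref_seg$n_strides)) {
      o <- ref_seg$strides$onset[i]; f2 <- ref_seg$strides$offset[i]
      dur <- (f2 - o) / rec$frame_rate
      phases <- setNames(rep(NA_real_, length(others)), others)
      ok <- TRUE
      for (lb in others) {
        rc <- lm_cols(reference_limb); oc <- lm_cols(lb)
        ph <- vapply(1:2, function(k)
          relative_phase(rec$x[fr, rc[k]], rec$x[fr, oc[k]], o, f2,
                         mean_subtract = mean_subtract), numeric(1))
        if (any(is.na(ph))) { drop_log["undefined"] <- drop_log["undefined"] + 1L; ok <- FALSE; break }
        if (!consistency_filter(ph[1], ph[2], tol)) {
          drop_log["consistency"] <- drop_log["consistency"] + 1L; ok <- FALSE; break
        }
        phases[lb] <- circ_mean(ph)
      }
      if (!ok) next
      duties <- vapply(setNames(feet, feet), function(lb) {
        s <- segs[[lb]]
        if (lb == reference_limb) return(duty_factor(s, o, f2))
        mid <- (o + f2) / 2
        j <- which(s$strides$onset <= mid & s$strides$offset > mid)
        if (length(j) == 0) return(NA_real_)
        duty_factor(s, s$strides$onset[j[1]], s$strides$offset[j[1]])
      }, numeric(1))
      hind <- mean(duties[c("LH", "RH")], na.rm = TRUE)
      fore <- mean(duties[c("LF", "RF")], na.rm = TRUE)
      gfr <- fr[o]:(fr[f2] - 1L)
      spd <- mean(posture$speed[gfr])
      so <- ref_seg$stance_onsets
      so_in <- so[so > o & so < f2]
      ref_x_bout <- .foot_mean_x(rec, reference_limb)[fr]
      slen <- if (length(so_in) >= 1) {
        so2 <- so[so > so_in[1]]
        if (length(so2) >= 1 && so2[1] <= length(fr)) {
          belt <- mean(posture$speed[fr[so_in[1]]:fr[so2[1]]]) * (so2[1] - so_in[1]) / rec$frame_rate
          belt - (ref_x_bout[so2[1]] - ref_x_bout[so_in[1]]) / 10
        } else spd * dur
      } else spd * dur
      hind_pair <- setdiff(c("LH", "RH"), reference_limb)
      hind_phase <- if (reference_limb %in% c("LH", "RH")) phases[[hind_pair]] else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        mouse_id = rec$metadata$mouse_id %||% NA_character_,
        trial_id = trial_id, ref_limb = reference_limb, bout = b,
        onset_frame = fr[o], offset_frame = fr[f2],
        duration = dur, speed = spd, stride_length = slen,
        duty_LF = duties[["LF"]], duty_RF = duties[["RF"]],
        duty_LH = duties[["LH"]], duty_RH = duties[["RH"]],
        duty_ratio_hind_fore = hind / fore,
        phase_LF = if ("LF" %in% others) phases[["LF"]] else NA_real_,
        phase_RF = if ("RF" %in% others) phases[["RF"]] else NA_real_,
        phase_LH = if ("LH" %in% others) phases[["LH"]] else NA_real_,
        phase_RH = if ("RH" %in% others) phases[["RH"]] else NA_real_,
        hindlimb_category = categorize_hindlimb_phase(hind_phase),
        snout_hump_angle = mean(posture$snout_hump_angle[gfr]),
        slope = rec$metadata$slope %||% NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "drop_log") <- drop_log
  class(out) <- c("stride_table", class(out))
  out
}

#' Write a stride table as tidy CSV
#'
#' @param tab a stride table from [build_stride_table()].
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
write_stride_table <- function(tab, path) {
  write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
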