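#' Per-frame limb contact states
#'
#' A limb is in stance from each of its stance onsets to its next swing
#' onset. Returns the 4-limb contact state per frame.
#'
#' @param segmentations named list of [segment_strides()] results for
#'   \code{LF, RF, LH, RH}, all over the same bout.
#' @param n_frames number of frames in the bout.
#' @return logical matrix (frames x 4, columns LF, RF, LH, RH);
#'   \code{TRUE} = stance.
#' @export
stance_mask <- function(segmentations, n_frames) {
  need <- c("LF", "RF", "LH", "RH")
  missing <- setdiff(need, names(segmentations))
  if (length(missing)) stop("unsegmented limb(s): ", paste(missing, collapse = ", "))
  out <- matrix(FALSE, n_frames, 4, dimnames = list(NULL, need))
  for (lb in need) {
    s <- segmentations[[lb]]
    if (length(s$stance_onsets) == 0) stop("unsegmented limb(s): ", lb)
    for (so in s$stance_onsets) {
      if (so > n_frames) next
      nxt <- s$swing_onsets[s$swing_onsets > so]
      hi <- if (length(nxt)) min(nxt) - 1L else n_frames
      out[so:min(hi, n_frames), lb] <- TRUE
    }
    # stance possibly in progress before the first detected swing onset
    first_sw <- min(s$swing_onsets)
    first_st <- min(s$stance_onsets)
    if (first_st > first_sw && first_sw > 1) out[seq_len(first_sw - 1L), lb] <- TRUE
  }
  out
}

# fixed grouping of the 16 raw contact states into 8 support categories
.support_categories <- c("four_limb", "three_limb", "diagonal",
                         "homologous_fore", "homologous_hind", "homolateral",
                         "single_limb", "no_contact")

.classify_state <- function(lf, rf, lh, rh) {
  k <- lf + rf + lh + rh
  if (k == 4) return("four_limb")
  if (k == 3) return("three_limb")
  if (k == 1) return("single_limb")
  if (k == 0) return("no_contact")
  if ((lf && rh) || (rf && lh)) return("diagonal")
  if (lf && rf) return("homologous_fore")
  if (lh && rh) return("homologous_hind")
  "homolateral" # (LF+LH) or (RF+RH)
}

#' Support-pattern time fractions for one stride
#'
#' Groups the 16 raw contact states into 8 categories (four-limb,
#' three-limb, diagonal pair, homologous fore/hind pair, homolateral pair,
#' single limb, no contact) and reports the fraction of stride time in each;
#' raw 16-state fractions are attached for transparency.
#'
#' @param contact logical matrix from [stance_mask()].
#' @param onset,offset stride interval \code{[onset, offset)}.
#' @return named numeric vector over the 8 categories, summing to 1, with a
#'   \code{"raw_states"} attribute (fractions over the 16 bit patterns).
#' @export
support_fractions <- function(contact, onset, offset) {
  fr <- onset:(offset - 1)
  stopifnot(max(fr) <= nrow(contact))
  m <- contact[fr, , drop = FALSE]
  cats <- apply(m, 1, function(r) .classify_state(r[["LF"]], r[["RF"]], r[["LH"]], r[["RH"]]))
  out <- setNames(numeric(length(.support_categories)), .support_categories)
  tb <- table(cats) / length(cats)
  out[names(tb)] <- as.numeric(tb)
  bits <- apply(m, 1, function(r) paste0(as.integer(r), collapse = ""))
  attr(out, "raw_states") <- table(factor(bits)) / length(bits)
  out
}

#' Support-pattern table for a stride table
#'
#' Convenience wrapper: recomputes per-limb segmentations per bout and the
#' 8-category support fractions for every stride in a [build_stride_table()]
#' result.
#'
#' @param rec the [trajectory_recording()] the table was built from.
#' @param tab the stride table.
#' @param min_period,min_prominence passed to [segment_strides()].
#' @return data.frame: one row per stride, 8 fraction columns plus the
#'   stride's identifying columns.
#' @export
support_profile_table <- function(rec, tab, min_period = NULL, min_prominence = NULL) {
  feet <- c("LF", "RF", "LH", "RH")
  rows <- list()
  for (b in unique(tab$bout)) {
    sub <- tab[tab$bout == b, ]
    fr <- min(sub$onset_frame):max(sub$offset_frame)
    segs <- lapply(setNames(feet, feet), function(f)
      segment_strides(.foot_mean_x(rec, f)[fr], rec$frame_rate,
                      min_period = min_period, min_prominence = min_prominence))
    if (any(vapply(segs, function(s) length(s$stance_onsets) == 0, logical(1)))) next
    cm <- stance_mask(segs, length(fr))
    for (i in seq_len(nrow(sub))) {
      o <- sub$onset_frame[i] - fr[1] + 1L
      f2 <- sub$offset_frame[i] - fr[1] + 1L
      sf <- support_fractions(cm, o, f2)
      rows[[length(rows) + 1]] <- cbind(
        sub[i, c("mouse_id", "trial_id", "bout", "onset_frame",
                 "hindlimb_category", "snout_hump_angle", "slope", "speed")],
        as.data.frame(as.list(sf))
      )
    }
  }
  do.call(rbind, rows)
}

#' PCA of limb-support profiles
#'
#' Centered (non-standardized) principal component analysis of the 8
#' support-category fractions, optionally split by hindlimb phase category.
#' Constant columns are dropped with a note; components are retained until
#' the cumulative variance reaches \code{var_target}; each loading vector's
#' sign is fixed so its largest-magnitude entry is positive.
#'
#' @param profiles data.frame or matrix containing the 8 fraction columns.
#' @param category optional factor; when given, one PCA per level
#'   (levels with fewer than \code{min_strides} strides are skipped).
#' @param var_target cumulative variance target for retention (default 0.9).
#' @param min_strides minimum strides per category (default 10).
#' @return for a single fit, a list of class \code{"support_pca"}:
#'   \code{loadings} (categories x PCs), \code{variance_explained} (\%),
#'   \code{selected} (PC indices kept), \code{projections},
#'   \code{dropped_columns}; for split fits, a named list of such objects.
#' @export
support_pca <- function(profiles, category = NULL, var_target = 0.9,
                        min_strides = 10) {
  cols <- intersect(.support_categories, colnames(profiles))
  M <- as.matrix(as.data.frame(profiles)[, cols, drop = FALSE])
  if (!is.null(category)) {
    category <- factor(category)
    out <- list()
    for (lv in levels(category)) {
      sel <- which(category == lv)
      if (length(sel) < min_strides) next
      out[[lv]] <- support_pca(M[sel, , drop = FALSE], var_target = var_target)
    }
    return(out)
  }
  if (nrow(M) < min_strides) stop("need at least ", min_strides, " strides")
  keep <- apply(M, 2, function(z) var(z) > 1e-14)
  dropped <- colnames(M)[!keep]
  M2 <- M[, keep, drop = FALSE]
  pc <- prcomp(M2, center = TRUE, scale. = FALSE)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  n_keep <- which(cumsum(ve) >= 100 * var_target)[1]
  structure(list(
    loadings = pc$rotation, variance_explained = ve,
    selected = seq_len(n_keep), projections = pc$x,
    dropped_columns = dropped, center = pc$center
  ), class = "support_pca")
}

#' @exportS3Method base::print
print.support_pca <- function(x, ...) {
  cat(sprintf("<support_pca: %d PCs retained (>= %.0f%% at PC%d)>\n",
              length(x$selected), sum(x$variance_explained[x$selected]),
              max(x$selected)))
  cat("variance explained (%):",
      paste(sprintf("%.1f", x$variance_explained), collapse = ", "), "\n")
  if (length(x$dropped_columns))
    cat("dropped constant columns:", paste(x$dropped_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Relate PC projections to posture covariates
#'
#' Linear mixed-effects trend per principal component with per-group
#' (mouse) intercepts: \code{projection ~ covariates + (1 | group)} via
#' lmerTest (falling back to plain least squares with fewer than three
#' groups). Reports the estimate, a Wald interval, the t statistic and a
#' significance flag per covariate and PC.
#'
#' @param projections matrix of per-stride PC projections (columns = PCs).
#' @param covariates data.frame of per-stride covariates (e.g. snout-hump
#'   angle, slope, their interaction).
#' @param group per-stride group ids (mouse).
#' @param pcs which PC columns to analyze (default: all).
#' @param conf_level interval level.
#' @return data.frame: one row per (PC, covariate) with \code{estimate},
#'   \code{lower}, \code{upper}, \code{t}, \code{significant}.
#' @export
project_and_regress <- function(projections, covariates, group,
                                pcs = seq_len(ncol(projections)),
                                conf_level = 0.95) {
  covariates <- as.data.frame(covariates)
  if (qr(as.matrix(cbind(1, covariates)))$rank < ncol(covariates) + 1)
    stop("singular design")
  g <- factor(group)
  rows <- list()
  for (j in pcs) {
    dat <- cbind(data.frame(.y = projections[, j], .g = g), covariates)
    if (var(dat$.y) < 1e-14) {
      for (v in names(covariates))
        rows[[length(rows) + 1]] <- data.frame(
          pc = j, covariate = v, estimate = 0, lower = 0, upper = 0,
          t = 0, significant = FALSE)
      next
    }
    form <- stats::as.formula(paste(".y ~", paste(names(covariates), collapse = " + "),
                                    "+ (1 | .g)"))
    use_lmer <- nlevels(droplevels(g)) >= 3
    if (use_lmer) {
      fit <- suppressWarnings(suppressMessages(
        lmerTest::lmer(form, data = dat,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))))
      sm <- coef(summary(fit))
      est <- sm[names(covariates), "Estimate"]
      se <- sm[names(covariates), "Std. Error"]
      tv <- sm[names(covariates), "t value"]
      df <- sm[names(covariates), "df"]
    } else {
      fit <- lm(stats::as.formula(
        paste(".y ~", paste(names(covariates), collapse = " + "))), data = dat)
      sm <- coef(summary(fit))
      est <- sm[names(covariates), "Estimate"]
      se <- sm[names(covariates), "Std. Error"]
      tv <- sm[names(covariates), "t value"]
      df <- fit$df.residual
    }
    q <- qt(1 - (1 - conf_level) / 2, df)
    lo <- est - q * se; hi <- est + q * se
    for (i in seq_along(names(covariates)))
      rows[[length(rows) + 1]] <- data.frame(
        pc = j, covariate = names(covariates)[i], estimate = unname(est[i]),
        lower = unname(lo[i]), upper = unname(hi[i]), t = unname(tv[i]),
        significant = unname(lo[i] > 0 | hi[i] < 0))
  }
  do.call(rbind, rows)
}

#' Flag PCs with congruent significant covariate effects across trial types
#'
#' @param reg_a,reg_b [project_and_regress()] tables from two trial types
#'   (e.g. head-height and slope trials).
#' @param covariate covariate name to compare.
#' @return data.frame of PCs significant in both tables with matching effect
#'   sign.
#' @export
congruent_pcs <- function(reg_a, reg_b, covariate) {
  a <- reg_a[reg_a$covariate == covariate & reg_a$significant, ]
  b <- reg_b[reg_b$covariate == covariate & reg_b$significant, ]
  common <- intersect(a$pc, b$pc)
  keep <- common[sign(a$estimate[match(common, a$pc)]) ==
                   sign(b$estimate[match(common, b$pc)])]
  data.frame(pc = keep)
}
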