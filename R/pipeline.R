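#' Pipeline configuration
#'
#' Bundles the analysis thresholds (all defaults as used throughout the
#' methods), resampling sizes, the synthetic cohort configuration and the
#' master seed. Thresholds are defaults of the corresponding functions, never
#' hard-coded in stage logic.
#'
#' @param thresholds named list; see Details for members and defaults.
#' @param cohort a [cohort_config()].
#' @param n_boot bootstrap replicates for regression intervals.
#' @param n_perm label shuffles for the lateralization permutation test.
#' @param seed master seed.
#' @details Threshold members: \code{likelihood_min} (0.95),
#'   \code{snout_hump_min_frac} (0.90), \code{ref_limb_min_frac} (0.80),
#'   \code{speed_threshold} (1 cm/s), \code{consistency_tol} (0.1 pi rad),
#'   \code{kde_kappa} (10), \code{kde_bins} (200), \code{phase_band}
#'   (0.2 pi rad), \code{standstill_min} (5 s), \code{cv_max} (0.05),
#'   \code{vif_max} (5).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(thresholds = list(), cohort = cohort_config(),
                            n_boot = 500, n_perm = 1000, seed = 1L) {
  def <- list(
    likelihood_min = 0.95, snout_hump_min_frac = 0.90, ref_limb_min_frac = 0.80,
    speed_threshold = 1, consistency_tol = 0.1 * pi,
    kde_kappa = 10, kde_bins = 200, phase_band = 0.2 * pi,
    standstill_min = 5, cv_max = 0.05, vif_max = 5
  )
  def[names(thresholds)] <- thresholds
  stopifnot(
    def$likelihood_min >= 0, def$likelihood_min <= 1,
    def$snout_hump_min_frac >= 0, def$snout_hump_min_frac <= 1,
    def$ref_limb_min_frac >= 0, def$ref_limb_min_frac <= 1,
    def$speed_threshold >= 0, def$consistency_tol > 0,
    def$kde_kappa > 0, def$kde_bins >= 4,
    def$standstill_min > 0, def$vif_max > 1
  )
  structure(list(thresholds = def, cohort = cohort,
                 n_boot = n_boot, n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration (TOML)
#'
#' Round-trips through the flat-TOML dialect with dotted section names.
#'
#' @param config a [pipeline_config()].
#' @param path TOML path.
#' @return \code{path}, or the reconstructed \code{"pipeline_config"}.
#' @export
write_pipeline_config <- function(config, path) {
  flat <- list(
    n_boot = config$n_boot, n_perm = config$n_perm, seed = config$seed,
    thresholds = config$thresholds,
    cohort = config$cohort[setdiff(names(config$cohort), "phase_link_params")],
    `cohort.phase_link_params` = config$cohort$phase_link_params
  )
  write_trial_metadata(flat, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- read_trial_metadata(path)
  co <- do.call(cohort_config, raw$cohort)
  pipeline_config(thresholds = raw$thresholds, cohort = co,
                  n_boot = raw$n_boot, n_perm = raw$n_perm, seed = raw$seed)
}

.pipeline_stages <- c("simulate", "strides", "loads", "density", "mixture",
                      "regress", "support", "bias", "cosmap", "all")

.trial_grid <- function(cfg) {
  co <- cfg$cohort
  hh <- expand.grid(mouse = seq_len(co$n_mice), head_height = co$head_heights,
                    slope = 0, type = "headheight", stringsAsFactors = FALSE)
  sl <- expand.grid(mouse = seq_len(co$n_mice), head_height = 44,
                    slope = co$slopes, type = "slope", stringsAsFactors = FALSE)
  g <- rbind(hh, sl)
  g$trial <- seq_len(nrow(g))
  g$seed <- cfg$seed + 1000L * g$mouse + g$trial
  # alternate stimulation side within each mouse
  g$stim_side <- ifelse(stats::ave(g$trial, g$mouse, FUN = seq_along) %% 2 == 0,
                        "left", "right")
  g
}

.read_cohort_strides <- function(out_dir) {
  p <- file.path(out_dir, "cohort_strides.csv")
  if (!file.exists(p)) stop("missing upstream artifact: ", p,
                            " (run the 'strides' stage first)")
  read.csv(p)
}

#' Run pipeline stages on the synthetic cohort
#'
#' Orchestrates the analysis end to end on generated data: \code{simulate}
#' writes trajectory and load trials (tidy + DeepLabCut CSV, TOML metadata,
#' ground-truth JSON); \code{strides} builds the cohort stride table;
#' \code{loads} the standstill load summaries; \code{density},
#' \code{mixture} and \code{regress} the homolateral phase statistics;
#' \code{support} the support-pattern PCA; \code{bias} the lateralization
#' classifier; \code{cosmap} the composed phase-vs-CoS curves; \code{all}
#' chains everything. Each run (re)writes \code{manifest.json} with the
#' seed, config hash and stage outputs.
#'
#' @param stage one of \code{simulate, strides, loads, density, mixture,
#'   regress, support, bias, cosmap, all}.
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param seed overrides \code{config$seed} when given.
#' @return invisibly, a named list of artifact paths written by the stage.
#' @export
run_pipeline <- function(stage, config = pipeline_config(),
                         out_dir = "gaitphase_out", seed = NULL) {
  stage <- match.arg(stage, .pipeline_stages)
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  co <- config$cohort
  artifacts <- list()

  if (stage == "all") {
    for (st in setdiff(.pipeline_stages, "all"))
      artifacts <- c(artifacts, run_pipeline(st, config, out_dir))
    return(invisible(artifacts))
  }

  grid <- .trial_grid(config)

  if (stage == "simulate") {
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      set.seed(g$seed)
      speed <- round(runif(1, 15, 40), 1)
      tr <- generate_trajectory_trial(
        co, g$mouse,
        covariates = list(head_height = g$head_height, slope = g$slope, speed = speed),
        seed = g$seed)
      tr$recording$metadata$stim_side <- g$stim_side
      tr$recording$metadata$trial_type <- g$type
      stem <- file.path(out_dir, sprintf("trial_%03d", g$trial))
      write_tidy_csv(tr$recording, paste0(stem, ".csv"))
      write_dlc_csv(tr$recording, paste0(stem, "_dlc.csv"))
      md <- tr$recording$metadata
      md$frame_rate <- co$frame_rate
      md$speed <- speed
      write_trial_metadata(md, paste0(stem, ".toml"))
      write_ground_truth(tr$truth, paste0(stem, "_truth.json"))
      lt <- generate_load_trial(co, list(head_height = g$head_height, slope = g$slope),
                                weight = co$weights[g$mouse], seed = g$seed + 1L)
      lt$metadata$mouse_id <- sprintf("m%02d", g$mouse)
      lt$metadata$trial_type <- g$type
      write_load_csv(lt, paste0(stem, "_load.csv"))
      lmd <- lt$metadata; lmd$foot_positions <- NULL
      write_trial_metadata(lmd, paste0(stem, "_load.toml"))
    }
    artifacts$trials <- out_dir
  }

  if (stage == "strides") {
    tabs <- list()
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      stem <- file.path(out_dir, sprintf("trial_%03d", g$trial))
      if (!file.exists(paste0(stem, ".csv")))
        stop("missing upstream artifact: ", paste0(stem, ".csv"),
             " (run the 'simulate' stage first)")
      md <- read_trial_metadata(paste0(stem, ".toml"))
      rec <- read_tidy_csv(paste0(stem, ".csv"), frame_rate = md$frame_rate,
                           metadata = md)
      ft <- filter_tracking(rec, likelihood_min = th$likelihood_min,
                            snout_hump_min_frac = th$snout_hump_min_frac,
                            ref_limb_min_frac = th$ref_limb_min_frac)
      if (!ft$included) next
      ps <- posture_series(ft$recording, speed_threshold = th$speed_threshold)
      tab <- build_stride_table(ft$recording, ps, tol = th$consistency_tol,
                                trial_id = sprintf("trial_%03d", g$trial))
      if (nrow(tab) == 0) next
      tab$trial_type <- g$type
      tab$stim_side <- g$stim_side
      tabs[[length(tabs) + 1]] <- as.data.frame(tab)
    }
    cohort_tab <- do.call(rbind, tabs)
    p <- file.path(out_dir, "cohort_strides.csv")
    write.csv(cohort_tab, p, row.names = FALSE)
    artifacts$strides <- p
  }

  if (stage == "loads") {
    rows <- list()
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      stem <- file.path(out_dir, sprintf("trial_%03d", g$trial))
      if (!file.exists(paste0(stem, "_load.csv")))
        stop("missing upstream artifact: ", paste0(stem, "_load.csv"))
      md <- read_trial_metadata(paste0(stem, "_load.toml"))
      md$foot_positions <- data.frame(
        foot = c("RF", "LF", "RH", "LH"),
        ap_cm = c(co$ap_half_cm, co$ap_half_cm, -co$ap_half_cm, -co$ap_half_cm),
        ml_cm = c(co$ml_half_cm, -co$ml_half_cm, co$ml_half_cm, -co$ml_half_cm))
      lt <- read_load_csv(paste0(stem, "_load.csv"), metadata = md)
      s <- tryCatch(summarize_load_trial(lt, standstill_min = th$standstill_min,
                                         cv_max = th$cv_max),
                    error = function(e) NULL)
      if (is.null(s)) next
      s$trial_type <- g$type
      rows[[length(rows) + 1]] <- as.data.frame(s)
    }
    p <- file.path(out_dir, "cohort_loads.csv")
    write.csv(do.call(rbind, rows), p, row.names = FALSE)
    artifacts$loads <- p
  }

  if (stage == "density") {
    tab <- .read_cohort_strides(out_dir)
    kde <- vm_kde(tab$phase_LF[!is.na(tab$phase_LF)],
                  kappa = th$kde_kappa, n_bins = th$kde_bins)
    p <- file.path(out_dir, "phase_density.csv")
    write.csv(data.frame(angle = kde$grid, density = kde$density), p,
              row.names = FALSE)
    artifacts$density <- p
  }

  if (stage == "mixture") {
    tab <- .read_cohort_strides(out_dir)
    fit <- fit_vm_mixture(tab$phase_LF[!is.na(tab$phase_LF)], seed = config$seed)
    uni <- unimodality_check(fit)
    p <- file.path(out_dir, "phase_mixture.json")
    jsonlite::write_json(list(
      bic = fit$bic,
      selected = fit$selected[c("mu", "kappa", "weight", "loglik", "bic",
                                "n_components", "kappa_capped")],
      unimodal = uni$unimodal, criterion = uni$criterion
    ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$mixture <- p
  }

  if (stage == "regress") {
    tab <- .read_cohort_strides(out_dir)
    out <- list()
    hh <- tab[tab$trial_type == "headheight" & !is.na(tab$phase_LF), ]
    if (nrow(hh) > 20) {
      f <- circ_linear_regression(
        hh$phase_LF, hh[, c("snout_hump_angle", "speed")], hh$mouse_id,
        n_boot = config$n_boot, seed = config$seed, vif_max = th$vif_max)
      out$headheight <- f[c("mu0", "beta", "kappa", "group_offsets", "centers",
                            "ci", "significant", "converged", "n")]
    }
    sl <- tab[tab$trial_type == "slope" & !is.na(tab$phase_LF), ]
    if (nrow(sl) > 20) {
      f <- circ_linear_regression(
        sl$phase_LF, sl[, c("slope", "speed")], sl$mouse_id,
        n_boot = config$n_boot, seed = config$seed, vif_max = th$vif_max)
      out$slope <- f[c("mu0", "beta", "kappa", "group_offsets", "centers",
                       "ci", "significant", "converged", "n")]
    }
    p <- file.path(out_dir, "phase_regression.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts$regress <- p
  }

  if (stage == "support") {
    tab <- .read_cohort_strides(out_dir)
    profs <- list()
    for (tid in unique(tab$trial_id)) {
      sub <- tab[tab$trial_id == tid, ]
      stem <- file.path(out_dir, paste0(sub$trial_id[1], ".csv"))
      md <- read_trial_metadata(sub0 <- sub("\\.csv$", ".toml", stem))
      rec <- read_tidy_csv(stem, frame_rate = md$frame_rate, metadata = md)
      pr <- support_profile_table(rec, sub)
      if (!is.null(pr)) profs[[length(profs) + 1]] <- pr
    }
    prof <- do.call(rbind, profs)
    p1 <- file.path(out_dir, "support_profiles.csv")
    write.csv(prof, p1, row.names = FALSE)
    fits <- support_pca(prof, category = prof$hindlimb_category)
    p2 <- file.path(out_dir, "support_pca_loadings.csv")
    ld <- do.call(rbind, lapply(names(fits), function(nm) {
      l <- as.data.frame(fits[[nm]]$loadings)
      l$category <- nm; l$support <- rownames(l); rownames(l) <- NULL; l
    }))
    write.csv(ld, p2, row.names = FALSE)
    artifacts$support <- c(p1, p2)
  }

  if (stage == "bias") {
    tab <- .read_cohort_strides(out_dir)
    tab <- tab[!is.na(tab$phase_RH) & !is.na(tab$stim_side), ]
    feats <- phase_features(tab[, c("phase_RH"), drop = FALSE])
    res <- permutation_test(feats, tab$stim_side, tab$mouse_id,
                            n_perm = config$n_perm, seed = config$seed)
    p <- file.path(out_dir, "bias_result.json")
    jsonlite::write_json(list(
      feature_set = "hindlimb", accuracy = res$accuracy,
      permutation_p = res$permutation_p, auc = res$auc,
      n_train = res$n_train, n_test = res$n_test
    ), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(res$roc_points, file.path(out_dir, "bias_roc.csv"), row.names = FALSE)
    artifacts$bias <- p
  }

  if (stage == "cosmap") {
    tab <- .read_cohort_strides(out_dir)
    lp <- file.path(out_dir, "cohort_loads.csv")
    if (!file.exists(lp)) stop("missing upstream artifact: ", lp)
    loads <- read.csv(lp)
    out <- list()
    curves <- list()
    for (tt in c("headheight", "slope")) {
      cov <- if (tt == "headheight") "snout_hump_angle" else "slope"
      ssub <- tab[tab$trial_type == tt & !is.na(tab$phase_LF), ]
      lsub <- loads[loads$trial_type == tt, ]
      if (nrow(ssub) < 20 || length(unique(lsub[[cov]])) < 4) next
      map <- build_cos_map(lsub, cov)
      fit <- circ_linear_regression(ssub$phase_LF,
                                    ssub[, cov, drop = FALSE], ssub$mouse_id,
                                    n_boot = config$n_boot, seed = config$seed)
      rng <- quantile(map$intercept + map$slope * ssub[[cov]], c(0.05, 0.95))
      rng[1] <- max(rng[1], map$cos_range[1]); rng[2] <- min(rng[2], map$cos_range[2])
      cv <- phase_shift_per_cos(fit, map, rng)
      out[[tt]] <- list(map = map[c("slope", "intercept", "covariate",
                                    "covariate_range", "cos_range")],
                        shift_over_range = cv$shift_over_range,
                        rad_per_cm = cv$rad_per_cm, shift_ci = cv$shift_ci)
      curves[[tt]] <- data.frame(trial_type = tt, cos_ap_cm = cv$cos_grid,
                                 phase = cv$phase, phase_shift = cv$phase_shift)
    }
    p <- file.path(out_dir, "cos_map.json")
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(do.call(rbind, curves), file.path(out_dir, "cos_phase_curves.csv"),
              row.names = FALSE)
    artifacts$cosmap <- p
  }

  cfg_path <- file.path(out_dir, "config.toml")
  write_pipeline_config(config, cfg_path)
  manifest <- list(
    stage = stage, seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("gaitphase")),
    artifacts = lapply(artifacts, function(p) basename(as.character(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(artifacts)
}
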