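#' von Mises kernel density estimate on the circle
#'
#' Mean of von Mises kernels centered at each observation, evaluated on a
#' regular grid and normalized so the trapezoidal integral over the circle
#' is 1.
#'
#' @param phases angles (rad), at least one.
#' @param kappa kernel concentration (default 10).
#' @param n_bins grid size over \code{[-pi, pi)} (default 200).
#' @return list of class \code{"phase_density"}: \code{grid} (rad),
#'   \code{density} (per rad), \code{kappa}, \code{n}.
#' @export
vm_kde <- function(phases, kappa = 10, n_bins = 200) {
  phases <- phases[!is.na(phases)]
  if (length(phases) < 1) stop("vm_kde needs at least one phase")
  grid <- -pi + (seq_len(n_bins) - 1) * 2 * pi / n_bins
  dens <- vapply(grid, function(g) mean(dvonmises(g, phases, kappa)), numeric(1))
  dens <- dens / (mean(dens) * 2 * pi) # periodic trapezoid = mean * 2 pi
  structure(list(grid = grid, density = dens, kappa = kappa, n = length(phases)),
            class = "phase_density")
}

#' @exportS3Method base::print
print.phase_density <- function(x, ...) {
  cat(sprintf("<phase_density: %d bins, kernel kappa = %g, n = %d>\n",
              length(x$grid), x$kappa, x$n))
  invisible(x)
}

# log-density matrix: rows = observations, cols = components
.vm_mix_logdens <- function(theta, mu, kappa, w) {
  K <- length(mu)
  ld <- matrix(0, length(theta), K)
  for (j in seq_len(K))
    ld[, j] <- log(w[j]) + dvonmises(theta, mu[j], kappa[j], log = TRUE)
  ld
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

# single EM run from given initial means
.vm_mix_em <- function(theta, mu0, kappa0, w0, kappa_max, max_iter, tol) {
  n <- length(theta)
  mu <- mu0; kappa <- kappa0; w <- w0
  ll_trace <- numeric(0)
  ll_old <- -Inf
  capped <- FALSE
  for (it in seq_len(max_iter)) {
    ld <- .vm_mix_logdens(theta, mu, kappa, w)
    lse <- .logsumexp_rows(ld)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    r <- exp(ld - lse)
    nk <- colSums(r)
    if (any(nk < 1e-8)) break
    w <- nk / n
    for (j in seq_along(mu)) {
      s <- sum(r[, j] * sin(theta)); c <- sum(r[, j] * cos(theta))
      mu[j] <- atan2(s, c)
      rbar <- sqrt(s^2 + c^2) / nk[j]
      kj <- a1_inv(min(rbar, 1 - 1e-12))
      if (!is.finite(kj) || kj > kappa_max) { kj <- kappa_max; capped <- TRUE }
      kappa[j] <- kj
    }
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
  }
  ld <- .vm_mix_logdens(theta, mu, kappa, w)
  ll <- sum(.logsumexp_rows(ld))
  list(mu = wrap_pi(mu), kappa = kappa, weight = w, loglik = ll,
       loglik_trace = ll_trace, kappa_capped = capped)
}

#' Fit von Mises mixture models by EM
#'
#' Fits mixtures with 1 to 4 components from multiple seeded restarts and
#' selects the component count by the Bayesian information criterion (lowest
#' BIC; ties favor fewer components). Concentrations are capped at
#' \code{kappa_max} against degeneracy on near-identical phases; capped fits
#' are flagged.
#'
#' @param phases angles (rad); each candidate count \code{K} requires at
#'   least \code{10 * K} observations.
#' @param n_components candidate component counts (subset of 1:4).
#' @param n_restarts EM restarts per count.
#' @param seed integer seed (restarts are deterministic given it).
#' @param kappa_max concentration cap (default 500).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list of class \code{"vm_mixture_set"}: \code{fits} (one
#'   \code{"vm_mixture"} per count), \code{selected} (the chosen fit),
#'   \code{bic} per count. Each fit holds \code{mu}, \code{kappa},
#'   \code{weight}, \code{loglik}, \code{bic}, \code{n_components},
#'   \code{kappa_capped}, \code{loglik_trace}.
#' @export
fit_vm_mixture <- function(phases, n_components = 1:4, n_restarts = 5,
                           seed = 1L, kappa_max = 500, max_iter = 500,
                           tol = 1e-8) {
  theta <- wrap_pi(phases[!is.na(phases)])
  n <- length(theta)
  n_components <- n_components[n_components * 10 <= n]
  if (length(n_components) == 0) stop("too few phases for any requested component count")
  fits <- list()
  for (K in n_components) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(seed + 1013L * r + K)
      mu0 <- if (r == 1) {
        # quantile-spread init along the circle from the data's mean direction
        wrap_pi(circ_mean(theta) + 2 * pi * (seq_len(K) - 1) / K)
      } else theta[sample.int(n, K)]
      f <- .vm_mix_em(theta, mu0, rep(2, K), rep(1 / K, K),
                      kappa_max, max_iter, tol)
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    p <- 3 * K - 1
    best$bic <- -2 * best$loglik + p * log(n)
    best$n_components <- K
    best$n <- n
    class(best) <- "vm_mixture"
    fits[[as.character(K)]] <- best
  }
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  sel <- fits[[which(bics <= min(bics) + 1e-9)[1]]] # ties -> fewer components
  structure(list(fits = fits, selected = sel, bic = bics),
            class = "vm_mixture_set")
}

#' @exportS3Method base::print
print.vm_mixture <- function(x, ...) {
  cat(sprintf("<vm_mixture: %d component(s), loglik %.2f, BIC %.2f%s>\n",
              x$n_components, x$loglik, x$bic,
              if (x$kappa_capped) ", kappa capped" else ""))
  for (j in seq_along(x$mu))
    cat(sprintf("  comp %d: mu = %+.3f rad (%.2f pi), kappa = %.2f, w = %.3f\n",
                j, x$mu[j], x$mu[j] / pi, x$kappa[j], x$weight[j]))
  invisible(x)
}

#' @exportS3Method base::print
print.vm_mixture_set <- function(x, ...) {
  cat("<vm_mixture_set> BIC by component count:\n")
  print(round(x$bic, 2))
  print(x$selected)
  invisible(x)
}

#' Unimodality verdict for a fitted mixture
#'
#' A phase sample is treated as unimodal when (1) the selected mixture has a
#' single component, (2) the dominant component carries at least
#' \code{dominant_min} of the weight, or (3) two components jointly carry at
#' least \code{dominant_min} and their mean directions differ by less than
#' \code{pair_sep_max}.
#'
#' @param fit a \code{"vm_mixture"} (or a \code{"vm_mixture_set"}, whose
#'   selected fit is used).
#' @param dominant_min weight threshold (default 0.8).
#' @param pair_sep_max circular separation threshold (default 0.2 pi rad).
#' @return list with \code{unimodal} (logical) and \code{criterion}
#'   (1, 2, 3, or NA when none holds).
#' @export
unimodality_check <- function(fit, dominant_min = 0.8, pair_sep_max = 0.2 * pi) {
  if (inherits(fit, "vm_mixture_set")) fit <- fit$selected
  if (fit$n_components == 1) return(list(unimodal = TRUE, criterion = 1L))
  if (max(fit$weight) >= dominant_min) return(list(unimodal = TRUE, criterion = 2L))
  K <- fit$n_components
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    if (fit$weight[i] + fit$weight[j] >= dominant_min &&
        circ_dist(fit$mu[i], fit$mu[j]) < pair_sep_max)
      return(list(unimodal = TRUE, criterion = 3L))
  }
  list(unimodal = FALSE, criterion = NA_integer_)
}

#' Circular-circular correlation
#'
#' Sine-moment correlation
#' \code{sum(sin(a - abar) sin(b - bbar)) / sqrt(sum(sin^2(a - abar)) *
#' sum(sin^2(b - bbar)))} with circular means \code{abar}, \code{bbar}.
#'
#' @param phase_a,phase_b equal-length angle vectors (rad), \code{n >= 3}.
#' @return correlation in \code{[-1, 1]}; \code{NA} (with a warning) when
#'   either circular mean is undefined (zero resultant).
#' @export
circ_circ_correlation <- function(phase_a, phase_b) {
  stopifnot(length(phase_a) == length(phase_b), length(phase_a) >= 3)
  am <- circ_mean(phase_a); bm <- circ_mean(phase_b)
  if (is.na(am) || is.na(bm)) {
    warning("undefined circular mean (zero resultant); correlation undefined")
    return(NA_real_)
  }
  sa <- sin(phase_a - am); sb <- sin(phase_b - bm)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den < 1e-12) {
    warning("degenerate spread; correlation undefined")
    return(NA_real_)
  }
  sum(sa * sb) / den
}

# ---- circular-linear regression (ML von Mises, Fisher-Lee atan link) ----

# negative log-likelihood and gradient for
# mu_i = mu0 + 2 atan(eta_i) + off_{g(i)}, eta = Xc %*% beta
.clr_nll <- function(par, theta, X, gidx, G) {
  p <- if (is.null(X)) 0L else ncol(X)
  mu0 <- par[1]
  beta <- if (p > 0) par[1 + seq_len(p)] else numeric(0)
  noff <- max(G - 1, 0)
  offs <- if (noff > 0) par[1 + p + seq_len(noff)] else numeric(0)
  logk <- par[length(par)]
  kappa <- exp(logk)
  eta <- if (p > 0) as.numeric(X %*% beta) else rep(0, length(theta))
  off_full <- if (G > 1) c(offs, -sum(offs))[gidx] else 0
  mu <- mu0 + 2 * atan(eta) + off_full
  n <- length(theta)
  -(kappa * sum(cos(theta - mu)) -
      n * (log(2 * pi) + log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa))
}

.clr_grad <- function(par, theta, X, gidx, G) {
  p <- if (is.null(X)) 0L else ncol(X)
  mu0 <- par[1]
  beta <- if (p > 0) par[1 + seq_len(p)] else numeric(0)
  noff <- max(G - 1, 0)
  offs <- if (noff > 0) par[1 + p + seq_len(noff)] else numeric(0)
  logk <- par[length(par)]
  kappa <- exp(logk)
  eta <- if (p > 0) as.numeric(X %*% beta) else rep(0, length(theta))
  off_full <- if (G > 1) c(offs, -sum(offs))[gidx] else 0
  mu <- mu0 + 2 * atan(eta) + off_full
  n <- length(theta)
  s <- sin(theta - mu)                      # dloglik/dmu_i = kappa * s_i
  g_mu0 <- -kappa * sum(s)
  g_beta <- if (p > 0) {
    dmu_deta <- 2 / (1 + eta^2)
    -kappa * as.numeric(t(X) %*% (s * dmu_deta))
  } else numeric(0)
  g_off <- if (noff > 0) {
    gs <- vapply(seq_len(G), function(g) sum(s[gidx == g]), numeric(1))
    -kappa * (gs[seq_len(noff)] - gs[G])
  } else numeric(0)
  g_logk <- -kappa * (sum(cos(theta - mu)) - n * a1_bessel(kappa))
  c(g_mu0, g_beta, g_off, g_logk)
}

.clr_fit_once <- function(theta, X, gidx, G, init = NULL) {
  p <- if (is.null(X)) 0L else ncol(X)
  if (is.null(init)) {
    r <- circ_resultant(theta)
    init <- c(circ_mean(theta), rep(0, p), rep(0, max(G - 1, 0)),
              log(max(a1_inv(min(r, 0.999)), 1e-3)))
  }
  op <- optim(init, .clr_nll, .clr_grad, theta = theta, X = X,
              gidx = gidx, G = G, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-10))
  op
}

#' Maximum-likelihood circular-linear regression
#'
#' Fits a von Mises model for a circular response with mean direction
#' \code{mu(x) = mu0 + 2 * atan(x' beta) + offset_group}, covariates centered
#' internally (the saturation midpoint is absorbed into the centering), and
#' sum-to-zero additive offsets per group. Coefficient intervals come from a
#' case-resampling bootstrap that resamples groups, then observations within
#' each resampled group; a coefficient is flagged significant when its
#' interval excludes zero.
#'
#' Covariates with a variance inflation factor above \code{vif_max} are
#' dropped with a warning before fitting; a rank-deficient design after
#' screening is an error naming the aliased columns.
#'
#' @param theta circular response (rad).
#' @param design data.frame or matrix of numeric covariates (may be
#'   \code{NULL} for an intercept-only fit, which reduces analytically to
#'   the circular mean).
#' @param group optional grouping factor (e.g. mouse id).
#' @param n_boot bootstrap replicates (default 500; 0 disables intervals).
#' @param seed integer seed for the bootstrap.
#' @param vif_max variance-inflation threshold (default 5).
#' @param conf_level interval level (default 0.95).
#' @return object of class \code{"circ_reg"}: \code{mu0}, \code{beta},
#'   \code{kappa}, \code{group_offsets}, \code{centers}, \code{ci}
#'   (per-coefficient bootstrap interval), \code{significant},
#'   \code{converged}, \code{loglik}, \code{n}, \code{boot} (replicate
#'   coefficient draws).
#' @export
circ_linear_regression <- function(theta, design = NULL, group = NULL,
                                   n_boot = 500, seed = 1L, vif_max = 5,
                                   conf_level = 0.95) {
  theta <- wrap_pi(theta)
  n <- length(theta)
  X <- NULL; centers <- NULL
  if (!is.null(design)) {
    X <- as.matrix(design)
    storage.mode(X) <- "double"
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    stopifnot(nrow(X) == n)
    if (ncol(X) >= 2) {
      vifs <- vapply(seq_len(ncol(X)), function(j) {
        r2 <- suppressWarnings(summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
        1 / max(1 - r2, 1e-12)
      }, numeric(1))
      if (any(vifs > vif_max)) {
        drop <- colnames(X)[vifs > vif_max]
        warning("dropping covariate(s) with VIF > ", vif_max, ": ",
                paste(drop, collapse = ", "))
        X <- X[, vifs <= vif_max, drop = FALSE]
      }
    }
    if (ncol(X) == 0) X <- NULL
  }
  if (!is.null(X)) {
    qx <- qr(cbind(1, X))
    if (qx$rank < ncol(X) + 1) {
      aliased <- colnames(X)[qx$pivot[-seq_len(qx$rank)] - 1]
      stop("rank-deficient design; aliased column(s): ",
           paste(aliased, collapse = ", "))
    }
    centers <- colMeans(X)
    X <- sweep(X, 2, centers)
  }
  g <- if (is.null(group)) factor(rep(1, n)) else factor(group)
  gidx <- as.integer(g); G <- nlevels(g)

  if (is.null(X) && G <= 1) {
    r <- circ_resultant(theta)
    out <- list(mu0 = circ_mean(theta), beta = numeric(0),
                kappa = a1_inv(min(r, 1 - 1e-12)),
                group_offsets = numeric(0), centers = NULL,
                ci = NULL, significant = logical(0), converged = TRUE,
                loglik = sum(dvonmises(theta, circ_mean(theta),
                                       a1_inv(min(r, 1 - 1e-12)), log = TRUE)),
                n = n, boot = NULL, groups = levels(g))
    class(out) <- "circ_reg"
    return(out)
  }

  op <- .clr_fit_once(theta, X, gidx, G)
  p <- if (is.null(X)) 0L else ncol(X)
  noff <- max(G - 1, 0)
  beta <- if (p > 0) setNames(op$par[1 + seq_len(p)], colnames(X)) else numeric(0)
  offs <- if (noff > 0) {
    o <- op$par[1 + p + seq_len(noff)]
    setNames(c(o, -sum(o)), levels(g))
  } else numeric(0)

  boot_mat <- NULL; ci <- NULL; sig <- setNames(rep(NA, p), names(beta))
  if (n_boot > 0 && p > 0) {
    set.seed(seed)
    boot_mat <- matrix(NA_real_, n_boot, p, dimnames = list(NULL, names(beta)))
    idx_by_g <- split(seq_len(n), gidx)
    for (b in seq_len(n_boot)) {
      gs <- sample(G, G, replace = TRUE)
      idx <- unlist(lapply(gs, function(gg) {
        ii <- idx_by_g[[gg]]
        ii[sample.int(length(ii), length(ii), replace = TRUE)]
      }))
      gb <- rep(seq_len(G), times = vapply(idx_by_g[gs], length, integer(1)))
      fb <- tryCatch(
        .clr_fit_once(theta[idx], X[idx, , drop = FALSE], gb, G,
                      init = op$par),
        error = function(e) NULL)
      if (!is.null(fb)) boot_mat[b, ] <- fb$par[1 + seq_len(p)]
    }
    a <- (1 - conf_level) / 2
    ci <- matrix(t(apply(boot_mat, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)),
                 ncol = 2, dimnames = list(names(beta), c("lower", "upper")))
    sig <- setNames(ci[, "lower"] > 0 | ci[, "upper"] < 0, rownames(ci))
  }
  out <- list(mu0 = wrap_pi(op$par[1]), beta = beta,
              kappa = exp(op$par[length(op$par)]),
              group_offsets = wrap_pi(offs), centers = centers,
              ci = ci, significant = sig,
              converged = op$convergence == 0, loglik = -op$value,
              n = n, boot = boot_mat, groups = levels(g))
  class(out) <- "circ_reg"
  out
}

#' @exportS3Method base::print
print.circ_reg <- function(x, ...) {
  cat(sprintf("<circ_reg: n = %d, kappa = %.2f, mu0 = %+.3f rad (%.2f pi)%s>\n",
              x$n, x$kappa, x$mu0, x$mu0 / pi,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (length(x$beta)) {
    tab <- data.frame(estimate = x$beta)
    if (!is.null(x$ci)) {
      tab$lower <- x$ci[, "lower"]; tab$upper <- x$ci[, "upper"]
      tab$significant <- x$significant
    }
    print(tab)
  }
  invisible(x)
}

#' Predicted mean direction from a circular-linear fit
#'
#' @param object a \code{"circ_reg"}.
#' @param newdata data.frame/matrix of covariates on the original scale.
#' @param group optional group ids whose offsets to add (population-level
#'   prediction when omitted).
#' @param ... unused.
#' @return mean directions (rad), wrapped.
#' @export
predict.circ_reg <- function(object, newdata = NULL, group = NULL, ...) {
  eta <- if (length(object$beta) > 0) {
    X <- as.matrix(newdata)[, names(object$beta), drop = FALSE]
    X <- sweep(X, 2, object$centers[names(object$beta)])
    as.numeric(X %*% object$beta)
  } else 0
  off <- if (!is.null(group)) object$group_offsets[as.character(group)] else 0
  wrap_pi(object$mu0 + 2 * atan(eta) + off)
}

#' Two-stage per-group circular regression
#'
#' Fits [circ_linear_regression()] separately within each group and pools
#' the per-group coefficients (mean, SD, one-sample t interval). A coarse,
#' conservative alternative to shared-slope fitting when slopes may vary by
#' animal.
#'
#' @param theta circular response (rad).
#' @param design covariate data.frame/matrix.
#' @param group grouping factor.
#' @param conf_level interval level.
#' @return data.frame with one row per coefficient: pooled mean, sd, t
#'   interval, number of groups.
#' @export
circ_regression_by_group <- function(theta, design, group, conf_level = 0.95) {
  g <- factor(group)
  fits <- lapply(levels(g), function(lv) {
    sel <- g == lv
    tryCatch(circ_linear_regression(theta[sel],
                                    design[sel, , drop = FALSE],
                                    n_boot = 0),
             error = function(e) NULL)
  })
  betas <- do.call(rbind, lapply(fits, function(f) if (is.null(f)) NULL else f$beta))
  if (is.null(betas) || nrow(betas) < 2) stop("too few groups with valid fits")
  alpha <- 1 - conf_level
  data.frame(
    coef = colnames(betas),
    mean = colMeans(betas),
    sd = apply(betas, 2, sd),
    lower = colMeans(betas) - qt(1 - alpha / 2, nrow(betas) - 1) *
      apply(betas, 2, sd) / sqrt(nrow(betas)),
    upper = colMeans(betas) + qt(1 - alpha / 2, nrow(betas) - 1) *
      apply(betas, 2, sd) / sqrt(nrow(betas)),
    n_groups = nrow(betas),
    row.names = NULL
  )
}
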