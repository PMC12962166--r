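test_that("von Mises KDE is normalized, symmetric and reflection-equivariant", {
  k1 <- vm_kde(0)
  expect_equal(k1$grid[which.max(k1$density)], 0, tolerance = 2 * pi / 200)
  # symmetry about the single kernel center
  expect_equal(k1$density[2:100], rev(k1$density[102:200]), tolerance = 1e-9)
  # uniform phases approach the uniform density
  set.seed(8)
  ku <- vm_kde(runif(10000, -pi, pi))
  expect_true(all(abs(ku$density - 1 / (2 * pi)) < 0.05 / (2 * pi)))
  # trapezoidal integral is 1 for arbitrary inputs
  for (i in 1:5) {
    kk <- vm_kde(rvonmises(50, runif(1, -pi, pi), runif(1, 0.5, 30)))
    expect_equal(sum(kk$density) * 2 * pi / 200, 1, tolerance = 1e-6)
  }
  # mirrored data yield the mirrored density
  x <- rvonmises(200, 0.7, 6)
  km <- vm_kde(-x)
  ko <- vm_kde(x)
  idx_m <- vapply(ko$grid, function(g) which.min(abs(wrap_pi(km$grid + g))), integer(1))
  expect_equal(km$density[idx_m], ko$density, tolerance = 1e-9)
  expect_error(vm_kde(numeric(0)), "at least one")
})

test_that("EM mixture fitting recovers generating parameters and is monotone", {
  set.seed(12)
  x1 <- rvonmises(2000, 0.54 * pi, 8)
  f1 <- fit_vm_mixture(x1, seed = 4)
  expect_equal(f1$selected$n_components, 1)
  expect_lt(circ_dist(f1$selected$mu, 0.54 * pi), 0.05 * pi)
  expect_equal(f1$selected$kappa, 8, tolerance = 1.5)
  # log-likelihood is non-decreasing across EM iterations, for every K
  for (f in f1$fits)
    expect_true(all(diff(f$loglik_trace) >= -1e-6))

  x2 <- c(rvonmises(1000, 0, 12), rvonmises(1000, pi, 12))
  f2 <- fit_vm_mixture(x2, seed = 4)
  expect_equal(f2$selected$n_components, 2)
  expect_equal(sort(f2$selected$weight), c(0.5, 0.5), tolerance = 0.05)
  mus <- sort(circ_dist(f2$selected$mu, 0))
  expect_lt(mus[1], 0.05 * pi)
  expect_gt(mus[2], 0.95 * pi)

  # identical phases: single capped component, flagged
  fd <- fit_vm_mixture(rep(1.3, 60), n_components = 1, seed = 2)
  expect_true(fd$selected$kappa_capped)
  expect_equal(fd$selected$kappa, 500)

  # deterministic given seed
  fa <- fit_vm_mixture(x2, seed = 9)
  fb <- fit_vm_mixture(x2, seed = 9)
  expect_identical(fa$bic, fb$bic)
  expect_error(fit_vm_mixture(rvonmises(5, 0, 1)), "too few")
})

test_that("unimodality criteria match their stated thresholds", {
  mk <- function(mu, w) structure(list(mu = mu, kappa = rep(10, length(mu)),
                                       weight = w, n_components = length(mu)),
                                  class = "vm_mixture")
  expect_equal(unimodality_check(mk(0, 1)), list(unimodal = TRUE, criterion = 1L))
  expect_equal(unimodality_check(mk(c(0, 2), c(0.85, 0.15))),
               list(unimodal = TRUE, criterion = 2L))
  u3 <- unimodality_check(mk(c(0, 0.1 * pi, 2), c(0.5, 0.45, 0.05)))
  expect_true(u3$unimodal); expect_equal(u3$criterion, 3L)
  u3b <- unimodality_check(mk(c(0, 0.5 * pi, 2), c(0.5, 0.45, 0.05)))
  expect_false(u3b$unimodal)
})

test_that("circular-circular correlation matches its closed form and null", {
  set.seed(3)
  a <- rvonmises(300, 0.3, 2)
  expect_equal(circ_circ_correlation(a, a), 1, tolerance = 1e-12)
  expect_equal(circ_circ_correlation(a, -a), -1, tolerance = 1e-12)
  u <- runif(10000, -pi, pi); v <- runif(10000, -pi, pi)
  expect_lt(abs(circ_circ_correlation(u, v)), 0.05)
})

test_that("intercept-only circular regression reduces to the circular mean", {
  set.seed(5)
  x <- rvonmises(400, 2.2, 6)
  f <- circ_linear_regression(x)
  expect_equal(f$mu0, circ_mean(x), tolerance = 1e-6)
  expect_equal(f$kappa, gaitphase:::a1_inv(circ_resultant(x)), tolerance = 1e-6)
})

test_that("circular regression recovers a known covariate effect", {
  cfg <- cohort_config(kappa_phase = 8, random_effect_sd = 0.1)
  d <- simulate_phase_cohort(cfg, n_mice = 6, strides_per_mouse = 250, seed = 21)
  f <- circ_linear_regression(d$phase, d[, "angle", drop = FALSE], d$mouse,
                              n_boot = 60, seed = 2)
  truth <- cfg$phase_link_params$beta_angle
  expect_true(f$converged)
  expect_equal(unname(f$beta[["angle"]]), truth, tolerance = 0.2)
  expect_gte(truth, f$ci["angle", "lower"] - 1e-9)
  expect_lte(truth, f$ci["angle", "upper"] + 1e-9)
  expect_true(f$significant[["angle"]])
  # wrap invariance of all phase statistics
  f2 <- circ_linear_regression(d$phase + 2 * pi, d[, "angle", drop = FALSE],
                               d$mouse, n_boot = 0)
  f3 <- circ_linear_regression(d$phase, d[, "angle", drop = FALSE],
                               d$mouse, n_boot = 0)
  expect_equal(f2$beta, f3$beta, tolerance = 1e-6)
  expect_equal(wrap_pi(f2$mu0 - f3$mu0), 0, tolerance = 1e-6)
  # prediction runs through the link
  mu_hat <- predict(f, data.frame(angle = c(150, 170)))
  expect_lt(circ_dist(mu_hat[1], phase_link_mu(cfg, 150)), 0.15)
  expect_lt(circ_dist(mu_hat[2], phase_link_mu(cfg, 170)), 0.15)
})

test_that("collinear designs are screened or rejected with named columns", {
  set.seed(6)
  n <- 200
  x <- runif(n, 0, 1)
  theta <- rvonmises(n, 0, 5)
  X <- data.frame(a = x, b = x + rnorm(n, 0, 1e-8), c = runif(n))
  expect_warning(circ_linear_regression(theta, X, n_boot = 0), "VIF")
  expect_error(
    circ_linear_regression(theta, data.frame(a = x, b = 2 * x), n_boot = 0,
                           vif_max = Inf),
    "aliased")
})

test_that("two-stage per-group regression pools per-mouse slopes", {
  cfg <- cohort_config(kappa_phase = 10, random_effect_sd = 0.05)
  d <- simulate_phase_cohort(cfg, n_mice = 5, strides_per_mouse = 200, seed = 3)
  tab <- circ_regression_by_group(d$phase, d[, "angle", drop = FALSE], d$mouse)
  truth <- cfg$phase_link_params$beta_angle
  expect_equal(tab$mean[tab$coef == "angle"], truth, tolerance = 0.3)
  expect_equal(tab$n_groups, 5)
})
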