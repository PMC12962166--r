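# segmentation stubs with explicit onsets
seg_stub <- function(swing, stance) {
  structure(list(swing_onsets = as.integer(swing), stance_onsets = as.integer(stance),
                 strides = data.frame(onset = head(swing, -1), offset = tail(swing, -1)),
                 n_strides = length(swing) - 1L),
            class = "stride_segmentation")
}

test_that("stance mask places limbs in stance between stance and swing onsets", {
  n <- 100
  # all limbs permanently in stance (stance onset 1, next swing beyond range)
  segs <- setNames(lapply(1:4, function(i) seg_stub(c(1, 200), 2)), c("LF", "RF", "LH", "RH"))
  m <- stance_mask(segs, n)
  expect_true(all(m[2:n, ]))
  expect_error(stance_mask(segs[c("LF", "RF", "LH")], n), "RH")
})

test_that("an ideal trot alternates between the two diagonal support pairs", {
  # duty 0.5, diagonal pairs in exact antiphase
  period <- 40
  mk <- function(offset) {
    sw <- seq(1 + offset, 400, by = period)
    st <- sw + period / 2
    seg_stub(sw, st[st < 400])
  }
  segs <- list(LH = mk(0), RF = mk(0), LF = mk(period / 2), RH = mk(period / 2))
  m <- stance_mask(segs, 360)
  states <- apply(m[41:320, ], 1, paste, collapse = "")
  counts <- table(states)
  # only the two diagonal states occur
  expect_setequal(names(counts), c("TRUEFALSEFALSETRUE", "FALSETRUETRUEFALSE"))
  sf <- support_fractions(m, 41, 41 + period)
  expect_equal(sf[["diagonal"]], 1)
  expect_equal(sum(sf), 1)
})

test_that("support fractions partition stride time for arbitrary states", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(runif(400) > 0.5, 100, 4, dimnames = list(NULL, c("LF", "RF", "LH", "RH")))
    sf <- support_fractions(m, 10, 90)
    expect_equal(sum(sf), 1, tolerance = 1e-12)
    expect_true(all(sf >= 0))
    raw <- attr(sf, "raw_states")
    expect_equal(sum(raw), 1, tolerance = 1e-12)
  }
  # all-stance stride
  ma <- matrix(TRUE, 50, 4, dimnames = list(NULL, c("LF", "RF", "LH", "RH")))
  sfa <- support_fractions(ma, 1, 50)
  expect_equal(sfa[["four_limb"]], 1)
  expect_equal(sum(sfa[names(sfa) != "four_limb"]), 0)
})

test_that("support fractions are invariant to frame-rate resampling", {
  set.seed(10)
  m <- matrix(runif(80) > 0.4, 20, 4, dimnames = list(NULL, c("LF", "RF", "LH", "RH")))
  m3 <- m[rep(seq_len(20), each = 3), ]
  f1 <- support_fractions(m, 1, 21)
  f3 <- support_fractions(m3, 1, 61)
  expect_equal(as.numeric(f1), as.numeric(f3), tolerance = 1e-12)
})

test_that("support PCA concentrates variance and fixes loading signs", {
  cats <- c("four_limb", "three_limb", "diagonal", "homologous_fore",
            "homologous_hind", "homolateral", "single_limb", "no_contact")
  # variation along exactly one axis between two fixed profiles
  set.seed(11)
  a <- c(0.5, 0.3, 0.2, 0, 0, 0, 0, 0)
  b <- c(0.1, 0.3, 0.6, 0, 0, 0, 0, 0)
  mix <- runif(100)
  P1 <- t(vapply(mix, function(t) t * a + (1 - t) * b, numeric(8)))
  colnames(P1) <- cats
  sp1 <- support_pca(P1)
  expect_equal(sp1$variance_explained[1], 100, tolerance = 1e-6)
  expect_equal(length(sp1$selected), 1)

  # two orthogonal archetype mixtures + small noise: 2 PCs reach 90%
  c1 <- c(1, -1, 0, 0, 0, 0, 0, 0) / sqrt(2)
  c2 <- c(0, 0, 1, -1, 0, 0, 0, 0) / sqrt(2)
  base <- rep(1 / 8, 8)
  P2 <- t(vapply(seq_len(200), function(i)
    base + rnorm(1, 0, 0.05) * c1 + rnorm(1, 0, 0.03) * c2 + rnorm(8, 0, 0.002),
    numeric(8)))
  colnames(P2) <- cats
  sp2 <- support_pca(P2)
  expect_lte(length(sp2$selected), 2)
  expect_gte(sum(sp2$variance_explained[1:2]), 90)
  # variance percentages always total 100
  expect_equal(sum(sp2$variance_explained), 100, tolerance = 1e-9)
  # sign convention: the largest-magnitude loading entry is positive
  for (j in seq_len(ncol(sp2$loadings)))
    expect_gt(sp2$loadings[which.max(abs(sp2$loadings[, j])), j], 0)
  # bitwise reproducibility under identical input ordering
  expect_identical(support_pca(P2)$loadings, sp2$loadings)
  # constant columns are dropped with a note
  expect_true("no_contact" %in% sp1$dropped_columns)
})

test_that("PC projections regress onto covariates with per-mouse intercepts", {
  set.seed(12)
  n <- 240
  mouse <- rep(sprintf("m%d", 1:4), each = n / 4)
  angle <- runif(n, 140, 180)
  # projections driven by angle plus mouse offsets and noise
  proj <- cbind(PC1 = 0.05 * angle + rep(rnorm(4, 0, 0.2), each = n / 4) + rnorm(n, 0, 0.3),
                PC2 = rnorm(n, 0, 0.5))
  res <- project_and_regress(proj, data.frame(angle = angle), mouse)
  r1 <- res[res$pc == 1 & res$covariate == "angle", ]
  expect_true(r1$estimate > r1$lower && r1$estimate < r1$upper)
  expect_equal(r1$estimate, 0.05, tolerance = 0.02)
  expect_true(r1$significant)
  # constant projections give a zero slope exactly
  res0 <- project_and_regress(cbind(PC1 = rep(2, n)), data.frame(angle = angle), mouse)
  expect_equal(res0$estimate, 0)
  expect_false(res0$significant)
  # singular designs are refused
  expect_error(project_and_regress(proj, data.frame(a = angle, b = 2 * angle), mouse),
               "singular")
})

test_that("congruent PCs require matching significance and sign across trial types", {
  ra <- data.frame(pc = c(1, 2), covariate = "angle", estimate = c(1, -1),
                   lower = c(0.5, -1.5), upper = c(1.5, -0.5), t = c(4, -4),
                   significant = c(TRUE, TRUE))
  rb <- data.frame(pc = c(1, 2), covariate = "angle", estimate = c(2, 1),
                   lower = c(1, 0.5), upper = c(3, 1.5), t = c(4, 4),
                   significant = c(TRUE, TRUE))
  expect_equal(congruent_pcs(ra, rb, "angle")$pc, 1)
})

test_that("support profiles from generated trials are complete partitions", {
  cfg <- noise_free_cfg(seed = 41L)
  tr <- generate_trajectory_trial(cfg, 1, list(head_height = 44, slope = 0, speed = 20),
                                  seed = 17)
  ps <- posture_series(tr$recording)
  tab <- build_stride_table(tr$recording, ps)
  prof <- support_profile_table(tr$recording, tab)
  expect_gt(nrow(prof), 3)
  frac_cols <- c("four_limb", "three_limb", "diagonal", "homologous_fore",
                 "homologous_hind", "homolateral", "single_limb", "no_contact")
  expect_equal(unname(rowSums(prof[, frac_cols])), rep(1, nrow(prof)),
               tolerance = 1e-9)
})
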