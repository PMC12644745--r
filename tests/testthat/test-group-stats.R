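test_that("the exact signed-rank p matches sign-flip enumeration", {
  # eight uniformly positive differences: p = 2 / 2^8
  t8 <- signed_rank_test(1:8)
  expect_identical(t8$method, "exact")
  expect_equal(t8$p_value, 0.0078125)
  # values symmetric about zero sit at the null centre
  expect_equal(signed_rank_test(c(1, -1, 2, -2, 3, -3))$p_value, 1)
  # random instances, with and without ties, n <= 12
  set.seed(19)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    d <- if (i %% 2) round(rnorm(n), 3) else sample(c(-3:-1, 1:3), n, TRUE)
    expect_equal(signed_rank_test(d)$p_value, enum_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  # tie-free exact p also agrees with the classical distribution
  for (i in 1:10) {
    d <- rnorm(10)
    expect_equal(signed_rank_test(d)$p_value,
                 stats::wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("large samples fall back to the corrected normal approximation", {
  set.seed(23)
  d <- rnorm(40, 0.2)
  t <- signed_rank_test(d)
  expect_identical(t$method, "normal_approximation")
  expect_equal(t$p_value,
               stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_warning(t0 <- signed_rank_test(numeric(5) * 0), "zero")
  expect_equal(t0$p_value, 1)
})

test_that("BH-FDR adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(0.037), 0.037)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(c(0.2, 0.9)), c(0.4, 0.9))
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(3:15, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_step_up(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12 & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the map-effect ANOVA matches hand sums of squares and edge cases", {
  # balanced 3 maps x 4 participants, one observation per cell
  set.seed(7)
  tab <- expand.grid(map_label = c("V1", "V2", "V3"),
                     participant = paste0("P", 1:4))
  tab$proportional_reduction <- rnorm(12)
  res <- map_effect_anova(tab)
  y <- matrix(tab$proportional_reduction, nrow = 3)  # maps x participants
  ssa <- 4 * sum((rowMeans(y) - mean(y))^2)
  ssb <- 3 * sum((colMeans(y) - mean(y))^2)
  sse <- sum((y - mean(y))^2) - ssa - ssb
  expect_equal(res$F, (ssa / 2) / (sse / 6), tolerance = 1e-10)
  expect_equal(res$df, c(2, 6))
  expect_equal(res$p_value, stats::pf(res$F, 2, 6, lower.tail = FALSE))
  # no map effect: per-map values identical across maps (residual variance
  # from the hemisphere replicate) give F = 0
  tab0 <- expand.grid(map_label = c("V1", "V2"), participant = c("P1", "P2"),
                      hemisphere = c("L", "R"))
  tab0$proportional_reduction <- 0.3 * as.integer(factor(tab0$participant)) +
    0.1 * as.integer(factor(tab0$hemisphere))
  res0 <- map_effect_anova(tab0)
  expect_lt(res0$F, 1e-10)
  expect_error(map_effect_anova(tab[tab$map_label == "V1", ]), "2 visual")
})

test_that("the ANOVA holds its size and detects a planted hierarchy", {
  maps <- c("V1", "V2", "V3", "hV4", "LO1", "LO2", "V3AB")
  base <- expand.grid(map_label = maps, participant = paste0("P", 1:8),
                      hemisphere = c("L", "R"))
  set.seed(101)
  # type-I error under a flat hierarchy
  rej <- replicate(200, {
    base$proportional_reduction <-
      rnorm(8)[as.integer(factor(base$participant))] + rnorm(nrow(base), 0, 0.3)
    map_effect_anova(base)$p_value < 0.05
  })
  expect_gte(mean(rej), 0.025)
  expect_lte(mean(rej), 0.075)
  # a strong V1 -> V3A/B gradient is detected and ordered correctly
  grad <- seq(0.25, 0.85, length.out = 7)
  hits <- replicate(100, {
    base$proportional_reduction <-
      grad[as.integer(factor(base$map_label, levels = maps))] +
      rnorm(nrow(base), 0, 0.1)
    res <- map_effect_anova(base)
    ext <- res$tukey[res$tukey$contrast %in% c("V3AB-V1", "V1-V3AB"), ]
    sgn <- if (ext$contrast == "V3AB-V1") ext$diff else -ext$diff
    res$p_value < 0.001 && sgn > 0 && ext$p_adj < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("regional correlations agree with the covariance formula", {
  a <- c(0.1, 0.4, 0.2, 0.8, 0.5, 0.3, 0.9, 0.6)
  expect_equal(region_correlations(a, 2 * a)$r, 1, tolerance = 1e-12)
  b <- c(0.3, 0.1, 0.5, 0.2, 0.9, 0.4, 0.7, 0.2)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- region_correlations(a, b)
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_false(res$normality_flag)
  # independent metrics: the mean correlation is centred at zero
  set.seed(59)
  rs <- replicate(1000, region_correlations(rnorm(16), rnorm(16))$r)
  expect_lt(abs(mean(rs)), 0.03)
  # degenerate input is reported, not guessed
  expect_true(is.na(region_correlations(rep(1, 8), b)$r))
  expect_error(region_correlations(a[1:3], b[1:3]), "at least 4")
})

test_that("tuned-effect summaries recover planted suppression and shifts", {
  # 6 tuned voxels in one hemisphere: delta R2 0.15, preference-change
  # slope -0.2 around intercept 0.3
  pref <- log(c(1.5, 2, 2.5, 3, 4, 5))
  meta <- data.frame(voxel_id = paste0("v", 1:6), participant = "P01",
                     hemisphere = "L", map_label = "LO1",
                     ecc_deg = 0.5, polar_deg = 0)
  fits <- do.call(rbind, lapply(1:6, function(i) {
    dp <- 0.3 - 0.2 * pref[i]
    data.frame(voxel_id = paste0("v", i),
               condition = c("low", "high", "changing"),
               model_class = "tuned", slope = NA_real_, baseline = 0,
               r2 = NA_real_,
               pref_log = c(pref[i] + dp / 2, pref[i] - dp / 2, pref[i]),
               width_log = 0.5, amplitude = 1,
               tuned_r2 = c(0.55, 0.40, 0.6),
               cv_r2_monotonic = NA_real_, cv_r2_tuned = NA_real_)
  }))
  ts <- tuned_effect_summary(meta, fits)
  expect_identical(ts$n_tuned, 6L)
  expect_equal(ts$delta_r2, 0.15, tolerance = 1e-12)
  expect_equal(ts$pref_change_slope, -0.2, tolerance = 1e-10)
})

test_that("the full battery runs over a synthetic example table", {
  maps <- c("V1", "V2", "V3", "hV4", "LO1", "LO2", "V3AB")
  grad <- seq(0.25, 0.85, length.out = 7)
  ex <- expand.grid(map_label = maps, participant = paste0("P", 1:8),
                    hemisphere = c("L", "R"), stringsAsFactors = FALSE)
  set.seed(71)
  ex$mean_slope_changing <- 1
  ex$mean_slope_low <- 1.1 + rnorm(nrow(ex), 0, 0.05)
  ex$mean_slope_high <- ex$mean_slope_low -
    grad[match(ex$map_label, maps)] + rnorm(nrow(ex), 0, 0.05)
  ex$mean_r2_low <- 0.5
  ex$mean_r2_high <- 0.4
  ex$included <- TRUE
  ex$proportional_reduction <-
    (ex$mean_slope_low - ex$mean_slope_high) / ex$mean_slope_changing
  gs <- group_statistics(ex)
  st <- gs$slope_tests
  expect_identical(sort(unique(st$test)),
                   sort(c("mean_slope_low", "mean_slope_high", "low_vs_high")))
  expect_true(all(st$p_adjusted >= st$p_value - 1e-12))
  # slopes are positive and reduced everywhere: all paired tests extreme
  expect_true(all(st$p_adjusted[st$test == "low_vs_high"] < 0.01))
  expect_lt(gs$anova$p_value, 1e-6)
  expect_identical(nrow(gs$map_correlations), as.integer(choose(7, 2)))
})
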