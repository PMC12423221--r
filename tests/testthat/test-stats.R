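test_that("shared-intercept fit equals the normal-equation solution", {
  set.seed(51)
  d <- sim_shared_intercept(4, 0.1, -0.18, sigma = 1)
  f <- fit_shared_intercept(d, "y")
  X <- cbind(1, d$duration * (d$treatment == "control"),
             d$duration * (d$treatment == "flood"))
  beta <- ols_fit(X, d$y)
  expect_equal(unname(c(f$intercept, f$slope_control, f$slope_flood)),
               unname(drop(beta)), tolerance = 1e-10)
  # exact recovery with zero noise, interaction p -> 0
  d0 <- sim_shared_intercept(4, 0.1, -0.18, sigma = 0)
  f0 <- fit_shared_intercept(d0, "y")
  expect_equal(f0$intercept, 4, tolerance = 1e-10)
  expect_equal(unname(f0$slope_control), 0.1, tolerance = 1e-10)
  expect_equal(unname(f0$slope_flood), -0.18, tolerance = 1e-10)
  expect_lt(f0$p_interaction, 1e-12)
  expect_equal(f0$r2, 1, tolerance = 1e-10)
})

test_that("interaction p-value is invariant to labels and affine response scaling", {
  set.seed(52)
  d <- sim_shared_intercept(2, 0.05, -0.1, sigma = 0.8)
  p1 <- fit_shared_intercept(d, "y")$p_interaction
  d2 <- d[rev(seq_len(nrow(d))), ]                      # reorder rows
  d2$treatment <- factor(d2$treatment, levels = c("flood", "control"))
  expect_equal(fit_shared_intercept(d2, "y")$p_interaction, p1,
               tolerance = 1e-12)
  d3 <- d; d3$y <- 100 + 7 * d3$y                       # affine rescale
  expect_equal(fit_shared_intercept(d3, "y")$p_interaction, p1,
               tolerance = 1e-10)
})

test_that("repeated-measures LRT: duplicated treatments give chi2 = 0, effects are detected", {
  # flood plants exact copies of control plants: treatment carries no
  # information, ML treatment terms vanish, chi2 = 0
  set.seed(53)
  days <- seq(0, 26, by = 3)
  base <- lapply(1:4, function(i) {
    data.frame(plant_id = paste0("c", i), treatment = "control", day = days,
               g_s = 0.2 + 0.01 * i + rnorm(length(days), 0, 0.02))
  })
  ctrl <- do.call(rbind, base)
  fld <- ctrl; fld$treatment <- "flood"; fld$plant_id <- sub("c", "f", fld$plant_id)
  lr0 <- lrt_flood_effect(rbind(ctrl, fld), window = c(0, 26))
  expect_equal(lr0$chi2, 0, tolerance = 1e-6)
  expect_equal(lr0$df, 2L)
  # strong suppression is detected
  fld2 <- fld; fld2$g_s <- fld2$g_s * 0.1
  lr1 <- lrt_flood_effect(rbind(ctrl, fld2), window = c(0, 26))
  expect_lt(lr1$p, 1e-6)
  # interaction-only reduction has one df
  expect_equal(lrt_flood_effect(rbind(ctrl, fld2), window = c(0, 26),
                                reduction = "interaction_only")$df, 1L)
})

test_that("null LRT p-values are approximately uniform", {
  # scaled down from the 200-simulation design (run-time budget); KS at 0.01
  set.seed(54)
  days <- seq(0, 26, by = 3)
  pvals <- replicate(60, {
    d <- expand.grid(plant = 1:10, day = days)
    d$plant_id <- paste0("p", d$plant)
    d$treatment <- ifelse(d$plant <= 5, "control", "flood")
    eff <- rnorm(10, 0, 0.03)
    d$g_s <- 0.2 + eff[d$plant] + rnorm(nrow(d), 0, 0.04)
    lrt_flood_effect(d, window = c(0, 26))$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("Spearman matrix equals rank-Pearson and is monotone-invariant", {
  set.seed(55)
  n <- 20
  d <- data.frame(a = rnorm(n), b = rnorm(n), c = rexp(n))
  m <- spearman_matrix(d, c("a", "b", "c"))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    oracle <- stats::cor(rank(d[[pair[1]]]), rank(d[[pair[2]]]))
    expect_equal(m$rho[pair[1], pair[2]], oracle, tolerance = 1e-12)
  }
  expect_equal(m$rho, t(m$rho))
  expect_equal(unname(diag(m$rho)), rep(1, 3))
  # monotone transforms leave rho unchanged
  d2 <- data.frame(a = exp(d$a), b = d$b^3, c = sqrt(d$c))
  m2 <- spearman_matrix(d2, c("a", "b", "c"))
  expect_equal(m2$rho, m$rho, tolerance = 1e-12)
  # extremes
  x <- 1:10
  expect_equal(spaflood:::spearman_pair(x, 2 * x + 3)[["rho"]], 1)
  expect_equal(spaflood:::spearman_pair(x, -x)[["rho"]], -1)
  expect_true(is.na(spaflood:::spearman_pair(x, rep(1, 10))[["rho"]]))
  # by-treatment grouping returns all three matrices
  d$treatment <- rep(c("control", "flood"), each = n / 2)
  g <- spearman_matrix(d, c("a", "b"), grouping = "by_treatment")
  expect_named(g, c("combined", "control", "flood"))
})

test_that("lenticel logistic recovers a symmetric threshold and flags degeneracies", {
  # symmetric 0/1 outcomes around day 11.5 with some overlap
  d <- data.frame(duration = rep(c(1, 3, 7, 10, 13, 16, 21, 25), each = 4),
                  treatment = "flood")
  d$lenticels <- as.integer(d$duration > 11.5)
  # perfect separation must be detected, not reported as estimates
  expect_error(lenticel_logistic(d), "separation")
  set.seed(56)
  d$lenticels <- rbinom(nrow(d), 1, plogis(0.4 * (d$duration - 13)))
  fit <- lenticel_logistic(d)
  expect_equal(fit$ed50, -fit$a / fit$b)
  expect_gt(fit$ed50, 5); expect_lt(fit$ed50, 21)
  d$lenticels <- 0
  expect_error(lenticel_logistic(d), "both outcome classes")
})

test_that("lenticel ED50 estimates are unbiased near the published values", {
  # scaled-down recovery study: generator ED50 15.3 d, slope 0.4
  set.seed(57)
  est <- replicate(60, {
    d <- data.frame(duration = rep(c(1, 3, 7, 10, 13, 16, 21, 25), each = 4),
                    treatment = "flood")
    d$lenticels <- rbinom(nrow(d), 1, plogis(0.4 * (d$duration - 15.3)))
    tryCatch(lenticel_logistic(d)$ed50, error = function(e) NA_real_)
  })
  expect_lt(abs(stats::median(est, na.rm = TRUE) - 15.3), 1.5)
})
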