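test_that("fixed seed gives identical output; design arithmetic holds", {
  cfg <- generator_config(seed = 71)
  e1 <- gen_environment(52, cfg); e2 <- gen_environment(52, cfg)
  expect_identical(e1, e2)
  h1 <- gen_harvest(cfg = cfg); h2 <- gen_harvest(cfg = cfg)
  expect_identical(h1, h2)
  expect_equal(nrow(h1), 96)
  expect_equal(sum(h1$treatment == "flood"), 64)
  expect_equal(sum(h1$treatment == "control"), 32)
  expect_setequal(unique(h1$duration), c(1, 3, 7, 10, 13, 16, 21, 25))
  # byte-identical CSV round trip
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_table_csv(gen_harvest(cfg = cfg), f1)
  write_table_csv(gen_harvest(cfg = cfg), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(f1, f2))
})

test_that("environment draws are positive with the stated means", {
  cfg <- generator_config(seed = 72)
  env <- gen_environment(1e4, cfg)
  expect_true(all(env$vpd > 0))
  expect_true(all(env$par > 0))
  expect_true(all(env$psi_soil == 0))
  expect_lt(abs(mean(env$vpd) - 1.95), 0.03)
  expect_lt(abs(mean(env$par) - 423), 6)
  expect_lt(abs(mean(env$t_air) - 27.4), 0.1)
})

test_that("zero-noise harvest equals the published linear predictors", {
  h <- gen_harvest(cfg = generator_config(seed = 1, noise_scale = 0))
  mg <- h[h$species == "Magnolia grandiflora", ]
  expect_equal(mg$k_total[mg$treatment == "flood" & mg$duration == 10][1],
               3.96 - 0.178 * 10, tolerance = 1e-12)
  expect_equal(mg$k_total[mg$treatment == "control" & mg$duration == 10][1],
               3.96 + 0.103 * 10, tolerance = 1e-12)
  qv <- h[h$species == "Quercus virginiana", ]
  expect_equal(qv$k_root[qv$treatment == "flood" & qv$duration == 7][1],
               3.32 + 0.143 * 7, tolerance = 1e-12)
})

test_that("harvest records satisfy positivity and lenticel constraints", {
  h <- gen_harvest(cfg = generator_config(seed = 73))
  for (v in c("g_s", "k_total", "k_stem", "k_root", "dm_fine_root",
              "dm_coarse_root", "la_ba", "basal_area")) {
    expect_true(all(h[[v]] > 0), label = paste(v, "positive"))
  }
  expect_true(all(h$psi_leaf < 0))
  expect_true(all(h$phi_psii > 0 & h$phi_psii < 1))
  expect_true(all(h$lenticels[h$treatment == "control"] == 0))
  expect_true(all(h$lenticels %in% c(0, 1)))
})

test_that("generated condition means track the linear predictors", {
  # pooled over seeds: |mean - predictor| < 3 SD / sqrt(n) per cell
  set.seed(74)
  hs <- do.call(rbind, lapply(1:6, function(s) {
    gen_harvest(cfg = generator_config(seed = 74 + s))
  }))
  mg <- hs[hs$species == "Magnolia grandiflora" & hs$treatment == "flood", ]
  for (dur in c(3, 13, 25)) {
    cell <- mg$k_total[mg$duration == dur]
    predictor <- max(3.96 - 0.178 * dur, 0.01 * 3.96)
    expect_lt(abs(mean(cell) - predictor), 3 * sd(cell) / sqrt(length(cell)))
  }
})

test_that("shared-intercept estimates from generated data are unbiased", {
  # scaled-down estimator-bias check (40 replicates), on a condition whose
  # linear predictor stays far from the positivity floor (k_root); for
  # conditions driven near zero (e.g. flooded k_total at long durations) the
  # floor truncates the noise and biases the refitted slope by construction
  set.seed(75)
  slopes <- t(replicate(40, {
    h <- gen_harvest(list(species_magnolia()),
                     cfg = generator_config(seed = sample.int(1e6, 1)))
    f <- fit_shared_intercept(h, "k_root")
    c(f$slope_control, f$slope_flood)
  }))
  mc_se <- apply(slopes, 2, sd) / sqrt(nrow(slopes))
  expect_lt(abs(mean(slopes[, 1]) - 0.005), 3 * mc_se[1])
  expect_lt(abs(mean(slopes[, 2]) - (-0.091)), 3 * mc_se[2])
})

test_that("timeseries: controls constant under constant env, flooded decline", {
  cfg <- generator_config(seed = 76, noise_scale = 0)
  env <- constant_env(days = 0:51)
  ts <- gen_timeseries(list(species_magnolia()), env, cfg)
  ctrl <- ts[ts$treatment == "control" & ts$plant_id == ts$plant_id[1], ]
  expect_equal(diff(range(ctrl$g_s)), 0, tolerance = 1e-8)
  fl <- ts[ts$treatment == "flood", ]
  fl1 <- fl[fl$plant_id == fl$plant_id[1], ]
  fl1 <- fl1[fl1$day <= 26, ]
  expect_true(all(diff(fl1$g_s) <= 1e-12))
  expect_equal(length(unique(ts$plant_id)), 10)
})

test_that("generated flood effect is detected by the mixed-model LRT", {
  # scaled-down power check (8 seeds; the design effect is large)
  cfg0 <- generator_config(seed = 1)
  detected <- vapply(1:8, function(s) {
    cfg <- generator_config(seed = 100 + s)
    env <- gen_environment(52, cfg)
    ts <- gen_timeseries(list(species_magnolia()), env, cfg)
    lrt_flood_effect(ts, window = c(0, 26))$p < 0.001
  }, logical(1))
  expect_gte(sum(detected), 7)
})
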