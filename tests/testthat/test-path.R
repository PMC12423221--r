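# simulate standardized data from the M2 structure (flood -> k_root,
# {flood, k_root} -> k_total, {par, vpd, k_total} -> g_s)
sim_m2 <- function(n = 48, b_fk_root = -0.37, b_fk_total = -0.78,
                   b_rk_total = 0.11, b_kt_gs = 0.6, b_vpd_gs = -0.4,
                   b_par_gs = 0.05) {
  flood <- rnorm(n); par <- rnorm(n); vpd <- rnorm(n)
  k_root <- b_fk_root * flood + rnorm(n, 0, sqrt(1 - b_fk_root^2))
  v_kt <- b_rk_total^2 + b_fk_total^2 + 2 * b_rk_total * b_fk_total * b_fk_root
  k_total <- b_rk_total * k_root + b_fk_total * flood +
    rnorm(n, 0, sqrt(max(1 - v_kt, 0.05)))
  g_s <- b_kt_gs * k_total + b_vpd_gs * vpd + b_par_gs * par + rnorm(n, 0, 0.5)
  data.frame(flood_duration = flood, k_root = k_root, k_total = k_total,
             par = par, vpd = vpd, g_s = g_s)
}

std <- function(d) scale(as.matrix(d))

test_that("candidate set has the required shared and varying paths", {
  mods <- candidate_path_models()
  expect_named(mods, c("M1", "M2", "M3", "M4"))
  shared <- c("par>g_s", "vpd>g_s", "k_total>g_s", "flood_duration>k_root",
              "k_root>k_total")
  for (m in mods) {
    keys <- paste(m$edges$from, m$edges$to, sep = ">")
    expect_true(all(shared %in% keys))
  }
  expect_true("flood_duration>k_total" %in%
                paste(mods$M2$edges$from, mods$M2$edges$to, sep = ">"))
  expect_true("flood_duration>g_s" %in%
                paste(mods$M3$edges$from, mods$M3$edges$to, sep = ">"))
  expect_equal(nrow(mods$M4$edges), 7)
  expect_error(path_model_spec("bad",
                               data.frame(from = c("g_s", "k_total"),
                                          to = c("k_total", "g_s"))),
               "cycle")
})

test_that("variable preparation standardises and validates transforms", {
  set.seed(61)
  h <- gen_harvest(cfg = generator_config(seed = 61))
  d <- harvest_to_path_data(h[h$species == "Magnolia grandiflora", ])
  expect_true(all(d$flood_duration[1:5] >= 0))
  m <- prepare_path_data(d)
  expect_equal(unname(colMeans(m)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(m, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # log transform rejects non-positive values with row identification
  d$g_s[3] <- 0
  expect_error(prepare_path_data(d), "rows: 3")
  # constant column
  d$g_s <- 1
  expect_error(prepare_path_data(d), "constant")
})

test_that("ML path coefficients equal per-equation least squares", {
  set.seed(62)
  mods <- candidate_path_models()
  for (i in 1:5) {
    dat <- std(sim_m2())
    for (m in mods[c("M1", "M4")]) {
      fit <- fit_path_model(m, dat)
      # oracle: per-equation OLS via lm, no intercept on centred data
      for (endo in unique(m$edges$to)) {
        preds <- m$edges$from[m$edges$to == endo]
        ols <- stats::lm(dat[, endo] ~ dat[, preds, drop = FALSE] - 1)
        want <- unname(coef(ols))
        got <- fit$edges$beta[fit$edges$to == endo][
          match(preds, fit$edges$from[fit$edges$to == endo])]
        expect_equal(got, want, tolerance = 1e-6)
      }
    }
  }
})

test_that("single-predictor betas on standardized data equal Pearson correlations", {
  set.seed(63)
  dat <- std(sim_m2())
  fit <- fit_path_model(candidate_path_models()$M1, dat)
  b <- fit$edges$beta[fit$edges$from == "flood_duration" &
                        fit$edges$to == "k_root"]
  expect_equal(b, cor(dat[, "flood_duration"], dat[, "k_root"]),
               tolerance = 1e-6)
})

test_that("AICc and Akaike weights match the closed formulas", {
  mk <- function(ll, k, n) structure(list(id = "x", loglik = ll, n_params = k,
                                          n = n, edges = data.frame()),
                                     class = "path_model_fit")
  n <- 48
  fits <- list(mk(-10, 3, n), mk(-11, 4, n), mk(-14, 2, n))
  ranked <- aicc_rank(fits, n)
  aicc_hand <- vapply(fits, function(f) {
    -2 * f$loglik + 2 * f$n_params +
      2 * f$n_params * (f$n_params + 1) / (n - f$n_params - 1)
  }, numeric(1))
  delta <- aicc_hand - min(aicc_hand)
  w_hand <- sort(exp(-delta / 2) / sum(exp(-delta / 2)), decreasing = TRUE)
  expect_equal(vapply(ranked, function(f) f$weight, numeric(1)), w_hand,
               tolerance = 1e-12)
  expect_equal(sum(w_hand), 1)
  expect_equal(ranked[[1]]$delta_aicc, 0)
  # invariance to input order and to a loglik constant shift
  ranked2 <- aicc_rank(rev(fits), n)
  expect_equal(vapply(ranked2, function(f) f$weight, numeric(1)), w_hand)
  shifted <- lapply(fits, function(f) { f$loglik <- f$loglik + 100; f })
  expect_equal(vapply(aicc_rank(shifted, n), function(f) f$weight, numeric(1)),
               w_hand, tolerance = 1e-12)
  # single model -> weight 1; equal AICc -> 0.5/0.5
  expect_equal(aicc_rank(list(mk(-5, 2, n)), n)[[1]]$weight, 1)
  eq <- aicc_rank(list(mk(-5, 2, n), mk(-5, 2, n)), n)
  expect_equal(vapply(eq, function(f) f$weight, numeric(1)), c(0.5, 0.5))
  expect_error(aicc_rank(list(mk(-5, 47, n)), n), "exceed")
})

test_that("coefficient averaging follows the cumulative-weight rule", {
  mk <- function(id, w, edges) structure(
    list(id = id, weight = w, edges = edges), class = "path_model_fit")
  e1 <- data.frame(from = "a_dummy", to = "b_dummy")  # placeholders unused
  # one model already above threshold: returned unchanged
  ed <- data.frame(from = "vpd", to = "g_s", beta = -0.4, se = 0.1)
  one <- list(mk("A", 0.6, ed), mk("B", 0.4, ed))
  avg <- average_paths(one, threshold = 0.55)
  expect_equal(avg$beta, -0.4)
  expect_equal(avg$n_selected[1], 1)
  # two selected with renormalized weights (0.6, 0.4): 0.6*1 + 0.4*0.5 = 0.8
  edA <- data.frame(from = "vpd", to = "g_s", beta = 1.0, se = 0.1)
  edB <- data.frame(from = "vpd", to = "g_s", beta = 0.5, se = 0.1)
  two <- list(mk("A", 0.48, edA), mk("B", 0.32, edB), mk("C", 0.2, edB))
  avg2 <- average_paths(two, threshold = 0.55)
  expect_equal(avg2$beta, 0.8, tolerance = 1e-12)
  # full-model averaging: absent path contributes zero
  edC <- data.frame(from = c("vpd", "par"), to = c("g_s", "g_s"),
                    beta = c(1, 0.6), se = c(0.1, 0.1))
  three <- list(mk("A", 0.48, edC), mk("B", 0.32, edB), mk("C", 0.2, edB))
  avg3 <- average_paths(three, threshold = 0.55)
  par_row <- avg3[avg3$from == "par", ]
  expect_equal(par_row$beta, 0.6 * 0.6, tolerance = 1e-12)
  cond <- average_paths(three, threshold = 0.55, method = "conditional")
  expect_equal(cond$beta[cond$from == "par"], 0.6, tolerance = 1e-12)
  expect_error(average_paths(list()), "empty")
})

test_that("pipeline recovers the generating flood-to-k_total coefficient", {
  # scaled down from the 200-replicate design (run-time budget)
  set.seed(64)
  mods <- candidate_path_models()
  est <- replicate(60, {
    dat <- std(sim_m2(n = 48))
    ranked <- aicc_rank(lapply(mods, fit_path_model, data = dat))
    avg <- average_paths(ranked)
    avg$beta[avg$from == "flood_duration" & avg$to == "k_total"]
  })
  expect_lt(abs(mean(est) - (-0.78)), 0.1)
})
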