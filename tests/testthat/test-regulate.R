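test_that("regulation limits: zero VPD gives G_max, vanishing supply gives 0", {
  net <- test_network()
  p0 <- regulated_conductance(list(vpd = 0, psi_soil = 0), net)
  expect_equal(p0$g_canopy, net$G_max)
  expect_equal(p0$e_flux, 0)
  tiny <- apply_flood(net, 1e-6, "whole_plant")
  pt <- regulated_conductance(list(vpd = 1.95, psi_soil = 0), tiny)
  expect_lt(pt$g_canopy / net$G_max, 1e-3)
  expect_lt(pt$e_flux, 1e-3)
})

test_that("fixed point equals a brute-force scan over the flux grid", {
  set.seed(41)
  for (i in 1:4) {
    net <- random_network()
    vpd <- runif(1, 0.3, 4)
    cf <- critical_flux(net)
    E <- seq(0, cf$E_crit, length.out = 2e4)
    D <- vpd / 101.3
    demand <- D * net$G_max * supply_slope(E, net) / cf$K0 / spaflood:::KG_HR_PER_MOL_S
    e_scan <- E[which.min(abs(E - demand))]
    p <- regulated_conductance(list(vpd = vpd, psi_soil = 0), net)
    e_got <- spaflood:::kg_hr_to_mol_s(p$e_flux)
    expect_equal(e_got, e_scan, tolerance = 2 * cf$E_crit / 2e4 / max(e_scan, 1e-9))
    expect_gte(p$g_canopy, 0)
    expect_lte(p$g_canopy, net$G_max * (1 + 1e-9))
    expect_lte(e_got, cf$E_crit * (1 + 1e-6))
  }
})

test_that("regulated conductance decreases strictly with VPD", {
  net <- test_network(G_max = 30000)
  g <- vapply(c(0.5, 1, 2, 3, 4), function(v) {
    regulated_conductance(list(vpd = v, psi_soil = 0), net)$g_canopy
  }, numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("flood_scale reproduces the published coefficient arithmetic", {
  frm <- flood_response_model(3.96, 0.103, -0.178, "k_total")
  expect_equal(flood_scale(0, frm), 1)                     # shared intercept
  expect_equal(flood_scale(10, frm), (3.96 - 1.78) / (3.96 + 1.03),
               tolerance = 1e-12)
  expect_equal(flood_scale(25, frm), 1e-3)                 # clamped at floor
  expect_equal(flood_scale(10, frm, mode = "relative_to_intercept"),
               (3.96 - 1.78) / 3.96, tolerance = 1e-12)
  # control trajectory crossing zero is an error
  bad <- flood_response_model(1, -0.2, -0.1)
  expect_error(flood_scale(10, bad), "non-positive")
  expect_error(flood_scale(-1, frm), "non-negative")
})

test_that("apply_flood scales components per the series identity", {
  net <- test_network()
  expect_identical(apply_flood(net, 1), net)
  half <- apply_flood(net, 0.5, "whole_plant")
  expect_equal(half$k_total_max, net$k_total_max / 2)
  for (nm in c("root", "stem", "leaf")) {
    expect_equal(half$curves[[nm]]$k_max, net$curves[[nm]]$k_max / 2)
  }
  # root-only scaling: 1 / (0.65 + 0.35/0.5) with default fractions
  rt <- apply_flood(net, 0.5, "root_component")
  expect_equal(rt$k_total_max / net$k_total_max, 1 / (0.65 + 0.35 / 0.5),
               tolerance = 1e-12)
  # only the root element's k_max changed
  expect_equal(rt$curves$root$k_max, net$curves$root$k_max * 0.5)
  expect_equal(rt$curves$stem$k_max, net$curves$stem$k_max)
  expect_error(apply_flood(net, 0), "scale")
  expect_error(apply_flood(net, 1.2), "scale")
  # regulated G is monotone in the whole-plant scale
  g <- vapply(c(1, 0.7, 0.4, 0.1), function(s) {
    regulated_conductance(list(vpd = 1.95, psi_soil = 0),
                          apply_flood(net, s, "whole_plant"))$g_canopy
  }, numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("predict_timeseries applies the flood window and persist policy", {
  net <- default_network(species_magnolia())
  frm <- flood_response_model(3.96, 0.103, -0.178, "k_total")
  env <- constant_env(days = c(0, 5, 10, 20, 26, 30, 40))
  # control: constant env -> constant predictions
  ctrl <- predict_timeseries(env, net, frm = NULL)
  expect_equal(diff(range(ctrl$g_canopy)), 0, tolerance = 1e-6)
  fl <- predict_timeseries(env, net, frm = frm, flood_window = c(0, 26))
  expect_equal(fl$scale[1], 1)
  expect_true(all(diff(fl$g_canopy[env$day <= 26]) < 1e-12))  # monotone decline
  # persist: post-flood days keep the day-26 scale
  s26 <- flood_scale(26, frm)
  expect_equal(fl$scale[env$day > 26], rep(s26, 2))
  # recover: scale relaxes linearly back toward 1
  rec <- predict_timeseries(env, net, frm = frm, flood_window = c(0, 26),
                            post_flood = "recover", recover_days = 14)
  expect_equal(rec$scale[env$day == 30], s26 + (1 - s26) * 4 / 14)
  expect_error(predict_timeseries(env[0, ], net), "empty")
})
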