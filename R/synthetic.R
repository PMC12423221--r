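# Synthetic greenhouse-experiment generator.
#
# Emulates the experimental design: two flood-sensitive tree species, eight
# flood durations (1, 3, 7, 10, 13, 16, 21, 25 d) with 4 flooded + 2 control
# plants per duration per species (N = 96 destructive harvests), and 5 + 5
# repeatedly measured plants per species followed for 51 days with the flood
# imposed on days 0-26. Condition means follow the published shared-intercept
# linear trajectories; the g_s timeseries is produced by the forward SPA
# model so every downstream stage sees data with the structure the analysis
# assumes.

HARVEST_DURATIONS <- c(1, 3, 7, 10, 13, 16, 21, 25)

# Inverse-CDF draw from a normal truncated below at `lower`, with the latent
# location solved so the *truncated* mean equals `mean` (the published
# greenhouse statistics are means of the positive quantities).
rtruncnorm_mean <- function(n, mean, sd, lower) {
  tmean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  mu <- stats::uniroot(function(m) tmean(m) - mean,
                       c(mean - 4 * sd, mean + sd))$root
  plo <- stats::pnorm(lower, mu, sd)
  stats::qnorm(stats::runif(n, plo, 1), mu, sd)
}

#' Species profile for the synthetic generator
#'
#' Bundles a species' published linear flood-response coefficients (one row
#' per physiological or structural condition), its lenticel dose-response,
#' initial size distribution, and the hydraulic-network defaults used to
#' forward-simulate its g_s timeseries.
#'
#' @param name species name
#' @param table1 data frame with columns `condition`, `intercept`,
#'   `se_intercept`, `slope_control`, `slope_flood`, `r2`
#' @param lenticel_ed50 flood duration (d) at 50% lenticel incidence
#' @param lenticel_slope logistic slope (d-1)
#' @param height_cm,basal_diam_mm `c(mean, sd)` initial size
#' @param network_args list passed to [plant_network()] (minus `G_max`,
#'   which is solved; see [default_network()])
#' @return object of class `species_profile`
#' @export
species_profile <- function(name, table1, lenticel_ed50, lenticel_slope = 0.4,
                            height_cm, basal_diam_mm, network_args = list()) {
  stopifnot(all(c("condition", "intercept", "se_intercept", "slope_control",
                  "slope_flood", "r2") %in% names(table1)))
  structure(list(name = name, table1 = table1,
                 lenticel_ed50 = lenticel_ed50,
                 lenticel_slope = lenticel_slope,
                 height_cm = height_cm, basal_diam_mm = basal_diam_mm,
                 network_args = network_args),
            class = "species_profile")
}

table1_row <- function(p, condition) {
  r <- p$table1[p$table1$condition == condition, ]
  if (nrow(r) != 1) stop("condition not in profile: ", condition)
  r
}

#' Published flood-response coefficients as a model object
#'
#' @param profile a [species_profile()]
#' @param condition condition name (e.g. `"k_total"`, `"k_root"`)
#' @return a [flood_response_model()]
#' @export
profile_frm <- function(profile, condition) {
  r <- table1_row(profile, condition)
  flood_response_model(r$intercept, r$slope_control, r$slope_flood, condition)
}

#' Built-in species profiles
#'
#' Southern magnolia (strongly flood-responsive: g_s suppressed ~91% during
#' flooding, k_total declining 0.178 units per flooded day) and live oak
#' (weakly responsive). Coefficients are the published shared-intercept
#' estimates; lenticel ED50s are 15.3 and 23.5 days.
#'
#' @return a [species_profile()]
#' @export
species_magnolia <- function() {
  t1 <- data.frame(
    condition = c("g_s", "phi_psii", "psi_leaf", "k_total", "k_stem",
                  "k_root", "dm_fine_root", "dm_coarse_root", "la_ba",
                  "basal_area"),
    intercept = c(0.065, 0.614, -0.738, 3.96, 28.36, 5.87, 100.6, 58.5,
                  1839, 21.8),
    se_intercept = c(0.010, 0.035, 0.037, 0.49, 5.45, 0.43, 9.2, 6.0, 97, 1.2),
    slope_control = c(0.0019, 0.0011, 0.0006, 0.103, 0.457, 0.005, 0.79,
                      0.64, -5.7, 0.16),
    slope_flood = c(-0.0030, -0.0129, -0.0004, -0.178, 0.2667, -0.091,
                    -1.46, 7.74, -3.0, 0.03),
    r2 = c(0.44, 0.42, 0.002, 0.51, 0.02, 0.18, 0.14, 0.05, 0.00, 0.00))
  species_profile("Magnolia grandiflora", t1, lenticel_ed50 = 15.3,
                  height_cm = c(34, 5), basal_diam_mm = c(5.9, 0.7))
}

#' @rdname species_magnolia
#' @export
species_quercus <- function() {
  t1 <- data.frame(
    condition = c("g_s", "phi_psii", "psi_leaf", "k_total", "k_stem",
                  "k_root", "dm_fine_root", "dm_coarse_root", "la_ba",
                  "basal_area"),
    intercept = c(0.232, 0.708, -1.565, 1.49, 26.31, 3.32, 159.9, 609.3,
                  599, 10.3),
    se_intercept = c(0.034, 0.017, 0.124, 0.52, 3.50, 0.84, 23.2, 84.7,
                     77, 1.1),
    slope_control = c(0.0021, -0.0007, 0.010, 0.221, -0.212, 0.251, 4.69,
                      1.05, -1.7, -0.02),
    slope_flood = c(0.0022, -0.0035, 0.0084, 0.043, 0.114, 0.143, 1.94,
                    7.74, -5.8, -0.11),
    r2 = c(0.02, 0.11, 0.02, 0.31, 0.03, 0.17, 0.06, 0.00, 0.00, 0.00))
  species_profile("Quercus virginiana", t1, lenticel_ed50 = 23.5,
                  height_cm = c(32, 10), basal_diam_mm = c(3.7, 0.8))
}

#' Default hydraulic network for a species profile
#'
#' `k_total_max` is seeded from the species' k_total intercept. `G_max` is
#' solved so that the regulated canopy conductance at the mean greenhouse
#' environment (VPD `vpd_ref`, saturated soil) equals the canopy-scale
#' observed conductance implied by the g_s and LA:BA intercepts — the
#' generator's control plants then transpire at realistic rates while still
#' being supply-regulated.
#'
#' @param profile a [species_profile()]
#' @param vpd_ref reference VPD (kPa) for the G_max solve
#' @return a [plant_network()]
#' @export
default_network <- function(profile, vpd_ref = 1.95) {
  k_tot <- table1_row(profile, "k_total")$intercept
  g_s0 <- table1_row(profile, "g_s")$intercept
  la_ba0 <- table1_row(profile, "la_ba")$intercept
  target_G <- g_s0 * la_ba0 * KG_HR_PER_MOL_S  # kg hr-1 m-2 basal
  args <- utils::modifyList(list(k_total_max = k_tot, G_max = 1),
                            profile$network_args)
  net0 <- do.call(plant_network, args)
  # at the fixed point with G = target_G the flux is D*G; read the supply
  # ratio there and scale G_max so that point *is* the fixed point
  D <- vpd_mole_fraction(vpd_ref)
  e_target <- kg_hr_to_mol_s(D * target_G)
  ratio <- supply_slope(e_target, net0, 0) / supply_slope(0, net0, 0)
  network_with(net0, G_max = target_G / ratio)
}

#' Generator configuration
#'
#' Defaults restate the published experiment: midday VPD 1.95 +/- 0.85 kPa,
#' air temperature 27.4 +/- 2.8 C, PAR 423 +/- 209 umol m-2 s-1, soil kept
#' saturated (psi_soil = 0); eight harvest durations with 4 flood + 2 control
#' plants each per species; 5 + 5 repeatedly measured plants per species over
#' 51 days with flooding on days 0-26 and measurement gaps of 1-5 days.
#' `noise_scale = 0` switches every stochastic component off (the linear
#' predictors are returned exactly).
#'
#' @param seed integer seed recorded in the config (callers pass it to the
#'   `gen_*` functions)
#' @param noise_scale multiplier on all residual SDs
#' @param sigma_ts_obs lognormal sigma of observation noise in the g_s
#'   timeseries
#' @param sigma_ts_plant lognormal sigma of the per-plant random intercept
#' @param lenticel_slope logistic slope (d-1) of lenticel incidence
#' @param flood_window flood days for the repeatedly measured plants
#' @param floor_frac positive floor for conductances/masses, as a fraction of
#'   the condition intercept
#' @param ts_impairment which published response drives the forward-simulated
#'   flood impairment (`"k_total"`: whole-plant; `"k_root"`)
#' @return list of class `generator_config`
#' @export
generator_config <- function(seed = 1L,
                             noise_scale = 1,
                             sigma_ts_obs = 0.20,
                             sigma_ts_plant = 0.15,
                             lenticel_slope = 0.4,
                             flood_window = c(0, 26),
                             floor_frac = 0.01,
                             ts_impairment = c("k_total", "k_root")) {
  structure(list(
    seed = as.integer(seed),
    env_mean = c(vpd = 1.95, t_air = 27.4, par = 423),
    env_sd = c(vpd = 0.85, t_air = 2.8, par = 209),
    env_floor = c(vpd = 0.05, t_air = 0, par = 1),
    durations = HARVEST_DURATIONS,
    n_flood = 4L, n_control = 2L,
    ts_n_per_treatment = 5L, ts_days = 51L,
    flood_window = flood_window,
    noise_scale = noise_scale,
    sigma_ts_obs = sigma_ts_obs,
    sigma_ts_plant = sigma_ts_plant,
    lenticel_slope = lenticel_slope,
    floor_frac = floor_frac,
    ts_impairment = match.arg(ts_impairment)),
    class = "generator_config")
}

#' Generate a midday greenhouse environment timeseries
#'
#' Truncated-normal draws per day for VPD, air temperature and PAR (location
#' adjusted so the truncated means equal the configured means); soil water
#' potential is 0 throughout (watered or flooded soil at saturation).
#'
#' @param days number of days (day 0 .. days-1)
#' @param cfg a [generator_config()]
#' @param seed RNG seed; defaults to the config's
#' @return data frame: `day`, `vpd`, `t_air`, `par`, `psi_soil`
#' @export
gen_environment <- function(days = 52, cfg = generator_config(), seed = cfg$seed) {
  stopifnot(days >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(v) {
    if (cfg$noise_scale == 0) return(rep_len(cfg$env_mean[[v]], days))
    rtruncnorm_mean(days, cfg$env_mean[[v]], cfg$env_sd[[v]] * cfg$noise_scale,
                    cfg$env_floor[[v]])
  }
  data.frame(day = seq_len(days) - 1,
             vpd = draw("vpd"), t_air = draw("t_air"), par = draw("par"),
             psi_soil = 0)
}

# Residual SD for one condition row. Conditions with a meaningful published
# R2 get the SD that reproduces it given the design's signal variance;
# conditions whose linear signal is negligible (R2 < 0.05) get the SD implied
# by the published intercept SE through the design matrix.
condition_sigma <- function(row, design) {
  mu <- ifelse(design$treatment == "flood", row$slope_flood,
               row$slope_control) * design$duration
  sd_signal <- sqrt(mean((mu - mean(mu))^2))
  if (row$r2 >= 0.05 && sd_signal > 0) {
    sd_signal * sqrt((1 - row$r2) / row$r2)
  } else {
    X <- cbind(1, design$duration * (design$treatment == "control"),
               design$duration * (design$treatment == "flood"))
    row$se_intercept / sqrt(solve(crossprod(X))[1, 1])
  }
}

#' Generate destructively harvested plant records
#'
#' For every species x duration x treatment cell, each condition is drawn
#' from its published linear predictor plus Gaussian residual noise (see
#' [generator_config()]); conductances, masses and areas are floored at a
#' small positive fraction of the intercept, leaf water potential is kept
#' negative and PhiPSII in (0, 1). Lenticels are Bernoulli draws from the
#' species' logistic dose-response for flooded plants and always absent in
#' controls. Midday VPD and PAR on the (staggered) harvest day are drawn from
#' the greenhouse distributions.
#'
#' @param profiles list of [species_profile()]s
#' @param cfg a [generator_config()]
#' @param seed RNG seed; defaults to the config's
#' @return data frame of harvest records (one row per plant)
#' @export
gen_harvest <- function(profiles = list(species_magnolia(), species_quercus()),
                        cfg = generator_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  id <- 0L
  for (p in profiles) {
    design <- expand.grid(duration = cfg$durations,
                          rep = seq_len(cfg$n_flood + cfg$n_control))
    design$treatment <- ifelse(design$rep <= cfg$n_flood, "flood", "control")
    n <- nrow(design)
    d <- data.frame(plant_id = sprintf("%s_H%02d", abbreviate(p$name, 2),
                                       id + seq_len(n)),
                    species = p$name,
                    treatment = design$treatment,
                    duration = design$duration)
    id <- id + n
    for (r in seq_len(nrow(p$table1))) {
      row <- p$table1[r, ]
      mu <- row$intercept + ifelse(d$treatment == "flood", row$slope_flood,
                                   row$slope_control) * d$duration
      sig <- cfg$noise_scale * condition_sigma(row, design)
      val <- mu + stats::rnorm(n, 0, sig)
      val <- switch(row$condition,
        psi_leaf = pmin(val, -1e-3),
        phi_psii = pmin(pmax(val, 0.01), 0.99),
        pmax(val, cfg$floor_frac * abs(row$intercept)))
      d[[row$condition]] <- val
    }
    pr <- stats::plogis(cfg$lenticel_slope * (d$duration - p$lenticel_ed50))
    d$lenticels <- ifelse(d$treatment == "flood",
                          stats::rbinom(n, 1, pr), 0L)
    if (cfg$noise_scale == 0) {
      d$lenticels <- ifelse(d$treatment == "flood",
                            as.integer(pr >= 0.5), 0L)
    }
    d$vpd <- if (cfg$noise_scale == 0) cfg$env_mean[["vpd"]] else
      rtruncnorm_mean(n, cfg$env_mean[["vpd"]], cfg$env_sd[["vpd"]],
                      cfg$env_floor[["vpd"]])
    d$par <- if (cfg$noise_scale == 0) cfg$env_mean[["par"]] else
      rtruncnorm_mean(n, cfg$env_mean[["par"]], cfg$env_sd[["par"]],
                      cfg$env_floor[["par"]])
    out[[p$name]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate the repeated-measures g_s timeseries
#'
#' One measurement schedule per run (day 0, then gaps drawn uniformly from
#' 1-5 days up to day `ts_days`). Per species, 5 control and 5 flood plants;
#' each plant's leaf-level g_s is the forward SPA prediction (flooded plants
#' carry the species' published flood impairment of `k_total_max`), converted
#' to the leaf basis via the LA:BA intercept, with a per-plant lognormal
#' random intercept and lognormal observation noise.
#'
#' @param profiles list of [species_profile()]s
#' @param env environment data frame from [gen_environment()] covering days
#'   0..`ts_days`
#' @param cfg a [generator_config()]
#' @param seed RNG seed; defaults to the config's
#' @return data frame: `plant_id`, `species`, `treatment`, `day`, `g_s`
#' @export
gen_timeseries <- function(profiles = list(species_magnolia(), species_quercus()),
                           env, cfg = generator_config(), seed = cfg$seed) {
  if (max(env$day) < cfg$ts_days) stop("environment must cover days 0..", cfg$ts_days)
  if (!is.null(seed)) set.seed(seed)
  days <- 0
  repeat {
    gap <- if (cfg$noise_scale == 0) 3 else sample(1:5, 1)
    nxt <- days[length(days)] + gap
    if (nxt > cfg$ts_days) break
    days <- c(days, nxt)
  }
  env_s <- env[match(days, env$day), , drop = FALSE]
  out <- list()
  for (p in profiles) {
    net <- default_network(p)
    la_ba <- table1_row(p, "la_ba")$intercept
    frm <- profile_frm(p, cfg$ts_impairment)
    pred_ctrl <- predict_timeseries(env_s, net, frm = NULL)
    # either driver scales the whole continuum; only the trajectory differs
    pred_flood <- predict_timeseries(env_s, net, frm = frm,
                                     flood_window = cfg$flood_window,
                                     target = "whole_plant")
    for (trt in c("control", "flood")) {
      pred <- if (trt == "control") pred_ctrl else pred_flood
      g_leaf <- kg_hr_to_mol_s(pred$g_canopy) / la_ba
      for (i in seq_len(cfg$ts_n_per_treatment)) {
        plant_eff <- if (cfg$noise_scale == 0) 1 else
          stats::rlnorm(1, 0, cfg$sigma_ts_plant * cfg$noise_scale)
        obs_eff <- if (cfg$noise_scale == 0) rep(1, length(days)) else
          stats::rlnorm(length(days), 0, cfg$sigma_ts_obs * cfg$noise_scale)
        out[[length(out) + 1L]] <- data.frame(
          plant_id = sprintf("%s_T_%s%d", abbreviate(p$name, 2),
                             substr(trt, 1, 1), i),
          species = p$name, treatment = trt, day = days,
          g_s = g_leaf * plant_eff * obs_eff)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
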