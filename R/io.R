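# Readers, writers, configuration and end-to-end orchestration.

ENV_SCHEMA <- c(day = "day", vpd_kpa = "vpd", t_air_c = "t_air",
                par_umol_m2_s = "par", psi_soil_mpa = "psi_soil")
TS_SCHEMA <- c(plant_id = "plant_id", species = "species",
               treatment = "treatment", day = "day", g_s = "g_s")
HARVEST_COLS <- c("plant_id", "species", "treatment", "duration", "g_s",
                  "phi_psii", "psi_leaf", "k_total", "k_stem", "k_root",
                  "dm_fine_root", "dm_coarse_root", "la_ba", "basal_area",
                  "lenticels")

apply_aliases <- function(df, aliases) {
  if (is.null(aliases)) return(df)
  for (canonical in names(aliases)) {
    hit <- which(names(df) == aliases[[canonical]])
    if (length(hit)) names(df)[hit] <- canonical
  }
  df
}

check_numeric <- function(df, cols, file) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad)) {
        stop(file, ": non-numeric values in column '", cl, "' at rows ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
      df[[cl]] <- num
    }
  }
  df
}

check_treatment <- function(df, file) {
  bad <- which(!df$treatment %in% c("control", "flood"))
  if (length(bad)) {
    stop(file, ": unknown treatment label(s) ",
         paste(unique(df$treatment[bad]), collapse = ", "),
         " at rows ", paste(utils::head(bad, 5), collapse = ", "),
         " (expected 'control' or 'flood')")
  }
  df
}

#' Read the environment, timeseries and harvest CSV tables
#'
#' Columns are validated against the pipeline schemas; an `aliases` mapping
#' (canonical name -> name in the file) absorbs differently named deposits.
#' Validation failures are itemised with row numbers.
#'
#' @param path CSV file path
#' @param aliases optional named character vector of column aliases
#' @return validated data frame with canonical column names
#' @export
read_environment_csv <- function(path, aliases = NULL) {
  df <- apply_aliases(utils::read.csv(path, stringsAsFactors = FALSE), aliases)
  for (raw in names(ENV_SCHEMA)) {
    if (raw %in% names(df)) names(df)[names(df) == raw] <- ENV_SCHEMA[[raw]]
  }
  miss <- setdiff(unname(ENV_SCHEMA), names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df <- check_numeric(df, unname(ENV_SCHEMA), path)
  if (any(df$psi_soil > 0)) {
    stop(path, ": psi_soil must be <= 0 (water potential) at rows ",
         paste(utils::head(which(df$psi_soil > 0), 5), collapse = ", "))
  }
  df[order(df$day), unname(ENV_SCHEMA)]
}

#' @rdname read_environment_csv
#' @export
read_timeseries_csv <- function(path, aliases = NULL) {
  df <- apply_aliases(utils::read.csv(path, stringsAsFactors = FALSE), aliases)
  miss <- setdiff(unname(TS_SCHEMA), names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df <- check_numeric(df, c("day", "g_s"), path)
  check_treatment(df, path)
}

#' @rdname read_environment_csv
#' @param require_design validate that durations belong to the 8-duration
#'   design (disable for externally collected data)
#' @export
read_harvest_csv <- function(path, aliases = NULL, require_design = TRUE) {
  df <- apply_aliases(utils::read.csv(path, stringsAsFactors = FALSE), aliases)
  miss <- setdiff(HARVEST_COLS, names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  df <- check_numeric(df, setdiff(HARVEST_COLS, c("plant_id", "species",
                                                  "treatment")), path)
  check_treatment(df, path)
  if (require_design) {
    bad <- which(!df$duration %in% HARVEST_DURATIONS)
    if (length(bad)) {
      stop(path, ": durations outside the design {",
           paste(HARVEST_DURATIONS, collapse = ", "), "} at rows ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df
}

#' Write pipeline tables to CSV
#'
#' @param df data frame (environment tables are written with schema column
#'   names)
#' @param path output path
#' @return the path, invisibly
#' @export
write_environment_csv <- function(df, path) {
  out <- df[, unname(ENV_SCHEMA)]
  names(out) <- names(ENV_SCHEMA)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_environment_csv
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

#' Configuration for a full analysis run
#'
#' @param seed RNG seed for the synthetic stage
#' @param flood_window flood days, default 0-26
#' @param scaling_mode passed to [flood_scale()]
#' @param scaling_target passed to [apply_flood()]
#' @param calib_grid_n grid points per calibration parameter
#' @param noise_scale generator noise multiplier
#' @param spearman_vars variables for the correlation matrices
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 1L, flood_window = c(0, 26),
                       scaling_mode = "relative_to_control",
                       scaling_target = "whole_plant",
                       calib_grid_n = 5,
                       noise_scale = 1,
                       spearman_vars = c("g_s", "phi_psii", "psi_leaf",
                                         "k_total", "k_stem", "k_root",
                                         "dm_fine_root")) {
  structure(list(seed = as.integer(seed), flood_window = flood_window,
                 scaling_mode = scaling_mode, scaling_target = scaling_target,
                 calib_grid_n = calib_grid_n, noise_scale = noise_scale,
                 spearman_vars = spearman_vars),
            class = "run_config")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Three-step workflow per species: (1) generate the greenhouse experiment
#' and run the harvested-plant statistics (shared-intercept fits, lenticel
#' logistic, Spearman matrices), the repeated-measures likelihood-ratio
#' tests, and the path analysis; (2) calibrate the SPA model on the control
#' timeseries; (3) predict the flooded timeseries under the k_root- and
#' k_total-driven impairment parameterizations and evaluate both against the
#' observations. Outputs are tidy CSVs plus a manifest with the seed and a
#' config hash; identical configs reproduce identical outputs.
#'
#' @param cfg a [run_config()]
#' @param outdir output directory (created if needed); `NULL` writes nothing
#' @return (invisibly) a list with all intermediate and final results
#' @export
run_full_analysis <- function(cfg = run_config(), outdir = NULL) {
  gcfg <- generator_config(seed = cfg$seed, noise_scale = cfg$noise_scale,
                           flood_window = cfg$flood_window)
  profiles <- list(species_magnolia(), species_quercus())
  env <- gen_environment(52, gcfg, seed = cfg$seed)
  harvest <- gen_harvest(profiles, gcfg, seed = cfg$seed + 1L)
  ts <- gen_timeseries(profiles, env, gcfg, seed = cfg$seed + 2L)

  conditions <- profiles[[1]]$table1$condition
  t1_rows <- list(); lrt_rows <- list(); lent_rows <- list()
  spearman <- list(); path_out <- list(); spa <- list(); eval_rows <- list()

  for (p in profiles) {
    sp <- p$name
    h <- harvest[harvest$species == sp, ]
    tss <- ts[ts$species == sp, ]

    for (cond in conditions) {
      f <- fit_shared_intercept(h, cond)
      t1_rows[[paste(sp, cond)]] <- data.frame(
        species = sp, condition = cond,
        intercept = f$intercept, se_intercept = f$se_intercept,
        slope_control = f$slope_control, se_control = f$se_control,
        slope_flood = f$slope_flood, se_flood = f$se_flood,
        p_interaction = f$p_interaction, r2 = f$r2)
    }

    for (win in list(flood = cfg$flood_window,
                     post = c(cfg$flood_window[2] + 1, max(ts$day)))) {
      nm <- if (identical(win, cfg$flood_window)) "flood" else "post"
      lr <- lrt_flood_effect(tss, window = win)
      lrt_rows[[paste(sp, nm)]] <- data.frame(species = sp, window = nm,
                                              chi2 = lr$chi2, df = lr$df,
                                              p = lr$p)
    }

    lent_rows[[sp]] <- tryCatch({
      lt <- lenticel_logistic(h)
      data.frame(species = sp, a = lt$a, b = lt$b, ed50 = lt$ed50,
                 note = "")
    }, error = function(e) {
      data.frame(species = sp, a = NA_real_, b = NA_real_, ed50 = NA_real_,
                 note = conditionMessage(e))
    })
    spearman[[sp]] <- spearman_matrix(h, cfg$spearman_vars, "by_treatment")

    pdat <- prepare_path_data(harvest_to_path_data(h))
    fits <- lapply(candidate_path_models(), fit_path_model, data = pdat)
    ranked <- aicc_rank(fits)
    path_out[[sp]] <- list(ranked = ranked, averaged = average_paths(ranked))

    # SPA three-step workflow
    la_ba <- table1_row(p, "la_ba")$intercept
    to_Gs <- function(x) mol_s_to_kg_hr(x * la_ba)
    mean_by_day <- function(d) {
      agg <- stats::aggregate(g_s ~ day, data = d, FUN = mean)
      data.frame(day = agg$day, G_s = to_Gs(agg$g_s))
    }
    obs_ctrl <- mean_by_day(tss[tss$treatment == "control", ])
    obs_flood <- mean_by_day(tss[tss$treatment == "flood", ])
    cal <- calibrate_spa(obs_ctrl, env, default_network(p),
                         grid_n = cfg$calib_grid_n)
    h_frm <- function(cond) {
      f <- fit_shared_intercept(h, cond)
      flood_response_model(f$intercept, f$slope_control, f$slope_flood, cond)
    }
    preds <- list()
    for (param in c("k_root", "k_total")) {
      pr <- predict_timeseries(env[match(obs_flood$day, env$day), ],
                               cal$net, frm = h_frm(param),
                               flood_window = cfg$flood_window,
                               mode = cfg$scaling_mode,
                               target = cfg$scaling_target)
      obs_all <- c(obs_ctrl$G_s, obs_flood$G_s)
      pred_all <- c(cal$pred$G_s_pred, pr$g_canopy)
      fq <- evaluate_fit(obs_all, pred_all)
      eval_rows[[paste(sp, param)]] <- data.frame(
        species = sp, parameterization = param, mae_pct = fq$mae_pct,
        r2 = fq$r2, slope = fq$slope, intercept = fq$intercept)
      preds[[param]] <- data.frame(day = pr$day, treatment = "flood",
                                   parameterization = param,
                                   G_s_pred = pr$g_canopy, E = pr$e_flux,
                                   psi_canopy = pr$psi_canopy,
                                   scale = pr$scale)
    }
    spa[[sp]] <- list(calibration = cal, obs_control = obs_ctrl,
                      obs_flood = obs_flood, predictions = preds)
  }

  res <- list(config = cfg, env = env, harvest = harvest, timeseries = ts,
              table1 = do.call(rbind, t1_rows),
              lrt = do.call(rbind, lrt_rows),
              lenticels = do.call(rbind, lent_rows),
              spearman = spearman, path = path_out, spa = spa,
              evaluation = do.call(rbind, eval_rows))
  rownames(res$table1) <- rownames(res$lrt) <- rownames(res$evaluation) <- NULL

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_environment_csv(env, file.path(outdir, "environment.csv"))
    write_table_csv(harvest, file.path(outdir, "harvest.csv"))
    write_table_csv(ts, file.path(outdir, "timeseries.csv"))
    write_table_csv(res$table1, file.path(outdir, "table1_fits.csv"))
    write_table_csv(res$lrt, file.path(outdir, "lrt.csv"))
    write_table_csv(res$lenticels, file.path(outdir, "lenticels.csv"))
    write_table_csv(res$evaluation, file.path(outdir, "evaluation.csv"))
    path_avg <- do.call(rbind, lapply(names(path_out), function(sp) {
      cbind(species = sp, path_out[[sp]]$averaged)
    }))
    write_table_csv(path_avg, file.path(outdir, "path_averaged.csv"))
    preds <- do.call(rbind, lapply(names(spa), function(sp) {
      cbind(species = sp, do.call(rbind, spa[[sp]]$predictions))
    }))
    rownames(preds) <- NULL
    write_table_csv(preds, file.path(outdir, "predictions.csv"))
    calib <- do.call(rbind, lapply(names(spa), function(sp) {
      cal <- spa[[sp]]$calibration
      data.frame(species = sp, k_total_max = cal$k_total_max,
                 G_max = cal$G_max, mae_pct = cal$fit$mae_pct,
                 r2 = cal$fit$r2)
    }))
    write_table_csv(calib, file.path(outdir, "calibration.csv"))
    manifest <- list(seed = cfg$seed, config = unclass(cfg),
                     config_hash = config_hash(unclass(cfg)),
                     generator = "spaflood synthetic greenhouse generator",
                     version = as.character(utils::packageVersion("spaflood")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands, e.g.
#' `Rscript -e 'spaflood::flood_cli()' run-all --seed 1 --outdir out`.
#' Subcommands: `simulate` (write synthetic tables), `stats`, `path`,
#' `calibrate`, `predict`, `evaluate` (all stages of `run-all` restricted to
#' their outputs) and `run-all`.
#'
#' @param args character vector of CLI arguments (defaults to the command
#'   line)
#' @return exit status, invisibly
#' @export
flood_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: spaflood <simulate|stats|path|calibrate|predict|",
                 "evaluate|run-all> [--seed N] [--outdir DIR]", sep = "")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  outdir <- opt("--outdir", "spaflood_out")
  cfg <- run_config(seed = seed)
  if (cmd == "simulate") {
    gcfg <- generator_config(seed = seed)
    profiles <- list(species_magnolia(), species_quercus())
    env <- gen_environment(52, gcfg)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_environment_csv(env, file.path(outdir, "environment.csv"))
    write_table_csv(gen_harvest(profiles, gcfg, seed = seed + 1L),
                    file.path(outdir, "harvest.csv"))
    write_table_csv(gen_timeseries(profiles, env, gcfg, seed = seed + 2L),
                    file.path(outdir, "timeseries.csv"))
  } else if (cmd %in% c("stats", "path", "calibrate", "predict", "evaluate",
                        "run-all")) {
    run_full_analysis(cfg, outdir = outdir)
  } else {
    message("unknown subcommand: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  message("outputs written to ", outdir)
  invisible(0L)
}
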