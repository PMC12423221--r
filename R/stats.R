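# Treatment-by-duration statistics for the harvested plants and the
# repeated-measures timeseries.

#' Shared-intercept treatment-by-duration linear model
#'
#' Fits `y = b0 + b1 * duration * I(control) + b2 * duration * I(flood)`:
#' both treatments share the duration-zero intercept (the flood treatment has
#' not yet acted at duration zero) and have treatment-specific slopes. The
#' interaction p-value is the Type II (hierarchy-respecting) F-test of the
#' slope split against the nested common-slope model `y = b0 + b * duration`.
#'
#' @param records data frame with columns `duration`, `treatment`
#'   (`"control"`/`"flood"`) and the response
#' @param response name of the response column
#' @return list of class `shared_intercept_fit`: `intercept`, `slope_control`,
#'   `slope_flood` with `se_*` companions, `p_interaction`, `r2`, `n`,
#'   `model` (the `lm` fit)
#' @export
fit_shared_intercept <- function(records, response) {
  stopifnot(response %in% names(records))
  d <- data.frame(y = records[[response]],
                  duration = records$duration,
                  treatment = factor(records$treatment,
                                     levels = c("control", "flood")))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$treatment)) < 2) {
    stop("both treatments must be present")
  }
  if (length(unique(d$duration)) < 3) stop("need at least 3 distinct durations")
  full <- stats::lm(y ~ duration:treatment, data = d)
  if (any(is.na(stats::coef(full)))) stop("singular design")
  reduced <- stats::lm(y ~ duration, data = d)
  cmp <- stats::anova(reduced, full)
  sm <- suppressWarnings(summary(full))  # zero-noise fixtures fit perfectly
  cf <- sm$coefficients
  ctrl <- grep("control", rownames(cf))
  fld <- grep("flood", rownames(cf))
  structure(list(intercept = cf[1, 1], se_intercept = cf[1, 2],
                 slope_control = cf[ctrl, 1], se_control = cf[ctrl, 2],
                 slope_flood = cf[fld, 1], se_flood = cf[fld, 2],
                 p_interaction = cmp$`Pr(>F)`[2],
                 r2 = sm$r.squared,
                 n = nrow(d),
                 model = full),
            class = "shared_intercept_fit")
}

#' @export
print.shared_intercept_fit <- function(x, ...) {
  cat(sprintf(paste0("<shared_intercept_fit> intercept %.4g +/- %.2g | ",
                     "control %.4g +/- %.2g | flood %.4g +/- %.2g | ",
                     "P(interaction) %.3g | R2 %.2f\n"),
              x$intercept, x$se_intercept, x$slope_control, x$se_control,
              x$slope_flood, x$se_flood, x$p_interaction, x$r2))
  invisible(x)
}

#' Likelihood-ratio test for a flood effect on the g_s timeseries
#'
#' Fits, by maximum likelihood, the mixed model
#' `g_s ~ treatment * day + (1 | plant_id)` against a reduced model with the
#' treatment terms removed (`reduction = "treatment_all"`, df = 2) or with
#' only the interaction removed (`"interaction_only"`, df = 1), and returns
#' the likelihood-ratio chi-square.
#'
#' @param ts_records data frame with `plant_id`, `treatment`, `day`, `g_s`
#' @param window inclusive day range to test, e.g. `c(0, 26)` for the flood
#'   period or `c(27, 51)` for post-flood recovery
#' @param reduction which treatment terms the reduced model drops
#' @return list: `chi2`, `df`, `p`, `messages` (fitting diagnostics, possibly
#'   empty), `full`, `reduced` (the `lmer` fits)
#' @export
lrt_flood_effect <- function(ts_records, window = c(0, 26),
                             reduction = c("treatment_all", "interaction_only")) {
  reduction <- match.arg(reduction)
  d <- ts_records[ts_records$day >= window[1] & ts_records$day <= window[2], ,
                  drop = FALSE]
  d$treatment <- factor(d$treatment, levels = c("control", "flood"))
  if (any(table(unique(d[c("plant_id", "treatment")])$treatment) < 2)) {
    stop("need at least 2 plants per treatment in the window")
  }
  msgs <- character(0)
  catcher <- function(expr) {
    withCallingHandlers(expr,
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
      })
  }
  full <- catcher(lme4::lmer(g_s ~ treatment * day + (1 | plant_id),
                             data = d, REML = FALSE))
  red_formula <- if (reduction == "treatment_all") {
    g_s ~ day + (1 | plant_id)
  } else {
    g_s ~ treatment + day + (1 | plant_id)
  }
  reduced <- catcher(lme4::lmer(red_formula, data = d, REML = FALSE))
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
  df <- if (reduction == "treatment_all") 2L else 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       messages = msgs, full = full, reduced = reduced)
}

# Average-rank Spearman correlation with t-approximation p-value.
spearman_pair <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 4) return(c(rho = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  c(rho = rho, p = p, n = n)
}

#' Pairwise Spearman correlation matrices
#'
#' Average-rank Spearman rho for every variable pair, with p-values from the
#' t approximation on n-2 degrees of freedom. Constant variables yield `NA`.
#' No multiple-testing correction is applied.
#'
#' @param records data frame containing the variables (and `treatment` when
#'   grouping)
#' @param variables character vector of column names to correlate
#' @param grouping `"combined"` for all plants pooled, or `"by_treatment"`
#'   for separate control/flood matrices plus the combined one
#' @return for `"combined"`, a list with matrices `rho`, `p`, `n`; for
#'   `"by_treatment"`, a named list of such lists (`combined`, `control`,
#'   `flood`)
#' @export
spearman_matrix <- function(records, variables,
                            grouping = c("combined", "by_treatment")) {
  grouping <- match.arg(grouping)
  one <- function(d) {
    k <- length(variables)
    rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
    for (i in seq_len(k)) {
      rho[i, i] <- 1; p[i, i] <- 0
      n[i, i] <- sum(stats::complete.cases(d[[variables[i]]]))
      for (j in seq_len(i - 1L)) {
        r <- spearman_pair(d[[variables[i]]], d[[variables[j]]])
        rho[i, j] <- rho[j, i] <- r[["rho"]]
        p[i, j] <- p[j, i] <- r[["p"]]
        n[i, j] <- n[j, i] <- r[["n"]]
      }
    }
    list(rho = rho, p = p, n = n)
  }
  if (grouping == "combined") return(one(records))
  list(combined = one(records),
       control = one(records[records$treatment == "control", , drop = FALSE]),
       flood = one(records[records$treatment == "flood", , drop = FALSE]))
}

#' Logistic dose-response model for hypertrophied lenticels
#'
#' Maximum-likelihood logistic regression of lenticel presence on flood
#' duration, fit to flood-treatment plants only (controls never form
#' hypertrophied lenticels and are excluded). The duration at which half the
#' plants are expected to have lenticels is `ed50 = -a/b`.
#'
#' @param flood_records data frame with `duration` and `lenticels` (0/1);
#'   rows with `treatment != "flood"` are dropped if a `treatment` column is
#'   present
#' @return list: `a` (intercept), `b` (slope, d-1), `ed50` (d), `se_a`,
#'   `se_b`, `model`
#' @export
lenticel_logistic <- function(flood_records) {
  d <- flood_records
  if ("treatment" %in% names(d)) d <- d[d$treatment == "flood", , drop = FALSE]
  y <- d$lenticels
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present among flooded plants")
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(lenticels ~ duration, data = d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE; invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  if (sep_warn || any(abs(cf) > 15)) {
    stop("complete (or quasi-complete) separation detected: the duration ",
         "threshold is sharper than the design can resolve; maximum-",
         "likelihood slope diverges. Profile the likelihood or pool ",
         "adjacent durations instead of trusting these estimates.")
  }
  se <- sqrt(diag(stats::vcov(fit)))
  list(a = unname(cf[1]), b = unname(cf[2]), ed50 = unname(-cf[1] / cf[2]),
       se_a = unname(se[1]), se_b = unname(se[2]), model = fit)
}
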