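# Shared fixtures and independent numerical oracles.

# small default network used across unit tests
test_network <- function(k_total_max = 4, G_max = 8000, ...) {
  plant_network(k_total_max = k_total_max, G_max = G_max, ...)
}

# random (but seeded) networks for property sweeps
random_network <- function() {
  plant_network(
    k_total_max = runif(1, 1, 8),
    G_max = runif(1, 2e3, 4e4),
    resistance_fractions = local({
      f <- runif(4, 0.5, 2); f <- f / sum(f)
      names(f) <- c("rhizosphere", "root", "stem", "leaf"); f
    }),
    weibull_b = stats::setNames(runif(3, 1.5, 5), c("root", "stem", "leaf")),
    weibull_c = stats::setNames(runif(3, 1.2, 4), c("root", "stem", "leaf")))
}

constant_env <- function(days = 0:51, vpd = 1.95) {
  data.frame(day = days, vpd = vpd, t_air = 27.4, par = 423, psi_soil = 0)
}

# ---- independent supply-function oracle -------------------------------------
# Tabulates each element's cumulative flux integral by trapezoid quadrature on
# a fine tension grid and chains linear-interpolation inverses: no shared code
# with the package's closed-form route.
oracle_chain <- function(net, dP = 1e-4, psi_max = 25) {
  grid <- seq(0, psi_max, by = dP)
  lapply(net$curves, function(comp) {
    k <- if (inherits(comp, "soil_params")) {
      rhizosphere_k(grid, comp)
    } else {
      vulnerability_k(grid, comp)
    }
    Fcum <- c(0, cumsum((k[-1] + k[-length(k)]) / 2 * diff(grid)))
    # drop the numerically flat tail so the inverse interpolant is single-valued
    keep <- c(TRUE, diff(Fcum) > 0)
    list(F = stats::approxfun(grid, Fcum, ties = "ordered"),
         Finv = stats::approxfun(Fcum[keep], grid[keep], ties = "ordered"))
  })
}

oracle_canopy_tension <- function(E, chain, psi_s = 0) {
  P <- psi_s
  for (el in chain) {
    P <- el$Finv(el$F(P) + E)
    if (is.na(P)) return(NA_real_)
  }
  P
}

oracle_supply_flux <- function(psi_c, chain, psi_s = 0, e_hi) {
  stats::uniroot(function(E) {
    p <- oracle_canopy_tension(E, chain, psi_s)
    if (is.na(p)) 1e9 else p - psi_c
  }, c(0, e_hi), tol = 1e-12)$root
}

# closed-form OLS (normal equations), independent of lm()
ols_fit <- function(X, y) solve(crossprod(X), crossprod(X, y))

# simulate harvested-plant responses from a shared-intercept model
sim_shared_intercept <- function(b0, b_ctrl, b_flood, sigma,
                                 durations = c(1, 3, 7, 10, 13, 16, 21, 25),
                                 n_flood = 4, n_control = 2) {
  d <- expand.grid(duration = durations, rep = seq_len(n_flood + n_control))
  d$treatment <- ifelse(d$rep <= n_flood, "flood", "control")
  mu <- b0 + ifelse(d$treatment == "flood", b_flood, b_ctrl) * d$duration
  d$y <- mu + rnorm(nrow(d), 0, sigma)
  d
}
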