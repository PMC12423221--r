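# Recursive path analysis: candidate causal models for stomatal conductance,
# maximum-likelihood estimation, AICc ranking and multimodel averaging.

PATH_VARS <- c("flood_duration", "k_root", "k_total", "par", "vpd", "g_s")

#' Define a candidate path model
#'
#' A recursive (acyclic) system of directed paths among the six analysis
#' variables: flood duration, k_root, k_total, PAR, VPD and g_s.
#'
#' @param id model label (e.g. `"M1"`)
#' @param edges data frame with character columns `from` and `to`
#' @return object of class `path_model_spec`
#' @export
path_model_spec <- function(id, edges) {
  stopifnot(is.character(id), all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  vars <- unique(c(edges$from, edges$to))
  if (!all(vars %in% PATH_VARS)) {
    stop("unknown variables: ", paste(setdiff(vars, PATH_VARS), collapse = ", "))
  }
  if (anyDuplicated(paste(edges$from, edges$to))) stop("duplicate paths")
  # cycle check by repeated leaf-stripping
  nodes <- vars; e <- edges
  repeat {
    sinks <- setdiff(nodes, e$from)
    if (length(sinks) == 0 && length(nodes) > 0) stop("model is not recursive (cycle)")
    nodes <- setdiff(nodes, sinks)
    e <- e[e$to %in% nodes, , drop = FALSE]
    if (length(nodes) == 0) break
  }
  structure(list(id = id, edges = edges), class = "path_model_spec")
}

#' The four candidate models of the flooding path analysis
#'
#' All models share the direct drivers of g_s (PAR, VPD, k_total) and the
#' hydraulic cascade flood duration -> k_root -> k_total. They differ in the
#' extra flood-duration paths: M1 none; M2 adds flood -> k_total (a hydraulic
#' constraint beyond the roots); M3 adds flood -> g_s (a non-hydraulic
#' stomatal constraint); M4 adds both.
#'
#' @return named list of four [path_model_spec()] objects
#' @export
candidate_path_models <- function() {
  base <- data.frame(
    from = c("par", "vpd", "k_total", "flood_duration", "k_root"),
    to   = c("g_s", "g_s", "g_s", "k_root", "k_total"),
    stringsAsFactors = FALSE)
  add <- function(e, from, to) rbind(e, data.frame(from = from, to = to))
  list(M1 = path_model_spec("M1", base),
       M2 = path_model_spec("M2", add(base, "flood_duration", "k_total")),
       M3 = path_model_spec("M3", add(base, "flood_duration", "g_s")),
       M4 = path_model_spec("M4", add(add(base, "flood_duration", "k_total"),
                                      "flood_duration", "g_s")))
}

#' Assemble the six path-analysis variables from harvest records
#'
#' Flood exposure is the treatment duration for flooded plants and 0 for
#' controls (which were never waterlogged, whatever their harvest day).
#'
#' @param harvest harvest-record data frame (needs `treatment`, `duration`,
#'   `k_root`, `k_total`, `par`, `vpd`, `g_s`)
#' @return data frame of the six variables, complete cases only
#' @export
harvest_to_path_data <- function(harvest) {
  d <- data.frame(
    flood_duration = ifelse(harvest$treatment == "flood", harvest$duration, 0),
    k_root = harvest$k_root, k_total = harvest$k_total,
    par = harvest$par, vpd = harvest$vpd, g_s = harvest$g_s)
  d[stats::complete.cases(d), , drop = FALSE]
}

#' Transform, centre and standardise the path-analysis variables
#'
#' Applies the configured normality-improving transforms (defaults: natural
#' log for g_s and k_total, square root for flood duration), then zero-centres
#' and scales every column to unit SD.
#'
#' @param records data frame containing the six path variables
#' @param transforms named list mapping variables to `"identity"`, `"log"` or
#'   `"sqrt"`
#' @return numeric matrix (n x 6) with attribute `transforms`
#' @export
prepare_path_data <- function(records,
                              transforms = list(g_s = "log", k_total = "log",
                                                flood_duration = "sqrt")) {
  stopifnot(all(PATH_VARS %in% names(records)))
  d <- records[, PATH_VARS]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  for (v in names(transforms)) {
    tr <- transforms[[v]]
    if (tr == "identity") next
    if (tr == "log") {
      bad <- which(d[[v]] <= 0)
      if (length(bad)) {
        stop("log transform of '", v, "' undefined for non-positive values ",
             "in rows: ", paste(utils::head(bad, 10), collapse = ", "))
      }
      d[[v]] <- log(d[[v]])
    } else if (tr == "sqrt") {
      if (any(d[[v]] < 0)) stop("sqrt transform of '", v, "' undefined for negatives")
      d[[v]] <- sqrt(d[[v]])
    } else stop("unknown transform: ", tr)
  }
  m <- as.matrix(d)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(colnames(m)[sds == 0], collapse = ", "))
  }
  m <- scale(m, center = TRUE, scale = sds)
  attr(m, "transforms") <- transforms
  m[, , drop = FALSE]
}

# ---- ML fitting of a recursive system ---------------------------------------
#
# Structural form: y = B y + Gamma x + zeta, with uncorrelated disturbances
# (diagonal Psi) and exogenous covariances fixed at their sample values.
# The Wishart discrepancy
#   F_ML = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p
# is minimised by BFGS with the analytic gradient
#   dF = sum(W * dSigma),  W = Sigma^-1 - Sigma^-1 S Sigma^-1.

path_implied_sigma <- function(theta, info) {
  nb <- nrow(info$edges); ne <- length(info$endo)
  betas <- theta[seq_len(nb)]
  psi <- exp(theta[nb + seq_len(ne)])
  B <- matrix(0, ne, ne, dimnames = list(info$endo, info$endo))
  G <- matrix(0, ne, length(info$exo), dimnames = list(info$endo, info$exo))
  for (r in seq_len(nb)) {
    f <- info$edges$from[r]; t <- info$edges$to[r]
    if (f %in% info$endo) B[t, f] <- betas[r] else G[t, f] <- betas[r]
  }
  A <- solve(diag(ne) - B)
  C <- G %*% info$Phi %*% t(G) + diag(psi, ne)
  Syy <- A %*% C %*% t(A)
  Syx <- A %*% G %*% info$Phi
  Sig <- matrix(0, info$p, info$p, dimnames = list(info$vars, info$vars))
  Sig[info$exo, info$exo] <- info$Phi
  Sig[info$endo, info$exo] <- Syx
  Sig[info$exo, info$endo] <- t(Syx)
  Sig[info$endo, info$endo] <- Syy
  list(Sigma = Sig, A = A, B = B, G = G, C = C, psi = psi)
}

path_fml <- function(theta, info) {
  im <- path_implied_sigma(theta, info)
  ch <- tryCatch(chol(im$Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  logdet + sum(info$S * chol2inv(ch)) - info$logdetS - info$p
}

path_fml_grad <- function(theta, info) {
  im <- path_implied_sigma(theta, info)
  Sinv <- solve(im$Sigma)
  W <- Sinv - Sinv %*% info$S %*% Sinv
  ne <- length(info$endo); nb <- nrow(info$edges)
  g <- numeric(length(theta))
  assemble <- function(dSyy, dSyx) {
    dS <- matrix(0, info$p, info$p, dimnames = list(info$vars, info$vars))
    dS[info$endo, info$endo] <- dSyy
    if (!is.null(dSyx)) {
      dS[info$endo, info$exo] <- dSyx
      dS[info$exo, info$endo] <- t(dSyx)
    }
    dS
  }
  PhiGt <- info$Phi %*% t(im$G)
  for (r in seq_len(nb)) {
    f <- info$edges$from[r]; t_ <- info$edges$to[r]
    if (f %in% info$endo) {
      Eij <- matrix(0, ne, ne, dimnames = dimnames(im$B)); Eij[t_, f] <- 1
      dA <- im$A %*% Eij %*% im$A
      dSyy <- dA %*% im$C %*% t(im$A)
      dSyy <- dSyy + t(dSyy)
      dSyx <- dA %*% im$G %*% info$Phi
    } else {
      dG <- matrix(0, ne, length(info$exo), dimnames = dimnames(im$G))
      dG[t_, f] <- 1
      M <- im$A %*% dG %*% PhiGt %*% t(im$A)
      dSyy <- M + t(M)
      dSyx <- im$A %*% dG %*% info$Phi
    }
    g[r] <- sum(W * assemble(dSyy, dSyx))
  }
  for (i in seq_len(ne)) {
    a <- im$A[, i, drop = FALSE]
    dSyy <- im$psi[i] * (a %*% t(a))
    g[nb + i] <- sum(W * assemble(dSyy, NULL))
  }
  g
}

#' Fit one candidate path model by maximum likelihood
#'
#' Minimises the Wishart discrepancy between the model-implied and sample
#' covariance matrices (sample covariances with divisor n; exogenous
#' variances and covariances fixed at their sample values and not counted as
#' parameters). Disturbances are uncorrelated. Standard errors come from the
#' inverse observed information.
#'
#' @param spec a [path_model_spec()]
#' @param data standardised data matrix from [prepare_path_data()]
#' @return object of class `path_model_fit`: `id`, `edges` (with `beta`,
#'   `se`), `loglik`, `n_params`, `n`, `f_ml`
#' @export
fit_path_model <- function(spec, data) {
  stopifnot(inherits(spec, "path_model_spec"))
  m <- as.matrix(data)
  n <- nrow(m)
  endo <- intersect(PATH_VARS, unique(spec$edges$to))
  exo <- setdiff(colnames(m), endo)
  k <- nrow(spec$edges) + length(endo)
  if (n <= k + 2) stop("too few observations for model ", spec$id)
  mc <- scale(m, center = TRUE, scale = FALSE)
  S <- crossprod(mc) / n
  info <- list(edges = spec$edges, endo = endo, exo = exo,
               vars = colnames(m), p = ncol(m),
               S = S, Phi = S[exo, exo, drop = FALSE],
               logdetS = determinant(S, logarithm = TRUE)$modulus)
  theta0 <- c(rep(0, nrow(spec$edges)), rep(0, length(endo)))
  opt <- stats::optim(theta0, path_fml, path_fml_grad, info = info,
                      method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  if (opt$convergence != 0) {
    stop("ML fit did not converge for model ", spec$id)
  }
  im <- path_implied_sigma(opt$par, info)
  if (inherits(tryCatch(chol(im$Sigma), error = identity), "error")) {
    stop("implied covariance not positive definite for model ", spec$id)
  }
  loglik <- -(n / 2) * (info$p * log(2 * pi) +
                          as.numeric(determinant(im$Sigma, TRUE)$modulus) +
                          sum(S * solve(im$Sigma)))
  ses <- rep(NA_real_, nrow(spec$edges))
  H <- tryCatch(stats::optimHess(opt$par, path_fml, path_fml_grad, info = info),
                error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve((n / 2) * H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)[seq_len(nrow(spec$edges))]
      ses <- ifelse(dv > 0, sqrt(dv), NA_real_)
    }
  }
  edges <- spec$edges
  edges$beta <- opt$par[seq_len(nrow(spec$edges))]
  edges$se <- ses
  structure(list(id = spec$id, edges = edges, loglik = loglik,
                 n_params = k, n = n, f_ml = opt$value),
            class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("<path_model_fit %s> loglik %.3f | k %d | n %d\n",
              x$id, x$loglik, x$n_params, x$n))
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Rank candidate fits by AICc and Akaike weight
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1)`; weights are the normalised
#' `exp(-delta/2)` relative likelihoods. Fits are returned sorted by weight
#' (descending), so the ranking is invariant to input order.
#'
#' @param fits list of [fit_path_model()] results
#' @param n sample size (taken from the fits when omitted)
#' @return list of fits, each augmented with `aicc`, `delta_aicc`, `weight`
#' @export
aicc_rank <- function(fits, n = NULL) {
  if (length(fits) == 0) stop("no fits supplied")
  if (is.null(n)) n <- fits[[1]]$n
  k <- vapply(fits, function(f) f$n_params, numeric(1))
  if (any(n <= k + 1)) stop("n must exceed k + 1 for the AICc correction")
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  aicc <- -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2) / sum(exp(-delta / 2))
  ord <- order(w, decreasing = TRUE)
  fits <- fits[ord]
  for (i in seq_along(fits)) {
    fits[[i]]$aicc <- aicc[ord][i]
    fits[[i]]$delta_aicc <- delta[ord][i]
    fits[[i]]$weight <- w[ord][i]
  }
  fits
}

#' Multimodel-averaged path coefficients
#'
#' Selects the smallest prefix of weight-ranked models whose cumulative
#' Akaike weight reaches `threshold`, renormalises the weights over the
#' selection, and averages every path's coefficient. Under full-model
#' averaging (default) a path absent from a selected model contributes 0 to
#' the average; conditional averaging renormalises over only the models
#' containing the path. Averaged SEs use the weight-renormalised
#' unconditional-variance formula.
#'
#' @param ranked_fits output of [aicc_rank()]
#' @param threshold cumulative-weight threshold (default 0.55)
#' @param method `"full"` or `"conditional"`
#' @return data frame: `from`, `to`, `beta`, `se`, `beta_over_se`,
#'   `included` (present in at least one selected model), `n_selected`
#' @export
average_paths <- function(ranked_fits, threshold = 0.55,
                          method = c("full", "conditional")) {
  method <- match.arg(method)
  if (length(ranked_fits) == 0) stop("empty fit list")
  w <- vapply(ranked_fits, function(f) f$weight, numeric(1))
  if (is.unsorted(rev(w))) stop("fits must be ranked by weight (use aicc_rank)")
  m <- which(cumsum(w) >= threshold)[1]
  if (is.na(m)) m <- length(ranked_fits)
  sel <- ranked_fits[seq_len(m)]
  wr <- w[seq_len(m)] / sum(w[seq_len(m)])

  all_edges <- unique(do.call(rbind, lapply(ranked_fits, function(f)
    f$edges[c("from", "to")])))
  rows <- lapply(seq_len(nrow(all_edges)), function(i) {
    f0 <- all_edges$from[i]; t0 <- all_edges$to[i]
    beta_i <- se_i <- numeric(m); present <- logical(m)
    for (j in seq_len(m)) {
      e <- sel[[j]]$edges
      hit <- which(e$from == f0 & e$to == t0)
      present[j] <- length(hit) == 1L
      beta_i[j] <- if (present[j]) e$beta[hit] else 0
      se_i[j] <- if (present[j]) e$se[hit] else 0
    }
    if (method == "conditional" && any(present)) {
      wj <- wr[present] / sum(wr[present])
      beta_i <- beta_i[present]; se_i <- se_i[present]
    } else {
      wj <- wr
    }
    beta <- sum(wj * beta_i)
    se <- sum(wj * sqrt(se_i^2 + (beta_i - beta)^2))
    data.frame(from = f0, to = t0, beta = beta, se = se,
               beta_over_se = if (se > 0) beta / se else NA_real_,
               included = any(present), n_selected = m)
  })
  do.call(rbind, rows)
}
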