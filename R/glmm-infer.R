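# Post-fit inference for the Poisson random-intercept GLMM: marginal-means
# pairwise contrasts with a single-step multivariate adjustment, parametric
# bootstrap confidence intervals, leave-one-group-out stability, and a
# simulation-based dispersion check.

# model-frame factor variables and their levels, from the stored table
fit_factor_levels <- function(fit) {
  vars <- all.vars(fit$fixed)
  lv <- lapply(vars, function(v) {
    col <- fit$table[[v]]
    if (is.factor(col)) levels(col) else if (is.character(col))
      levels(factor(col)) else NULL
  })
  names(lv) <- vars
  Filter(Negate(is.null), lv)
}

#' Pairwise contrasts of estimated marginal means
#'
#' Builds the grid of cells defined by `factors`, computes each cell's
#' marginal linear prediction (model-matrix rows averaged with equal weights
#' over the levels of the remaining factors, offset excluded), and tests all
#' pairwise differences on the link (log) scale with delta-method standard
#' errors. P-values are adjusted by the single-step multivariate-normal
#' method using the estimated correlation of the contrasts (the Tukey-style
#' adjustment for these non-linear mixed models), with Holm as fallback.
#'
#' @param fit a converged `"callgram_glmm"`.
#' @param factors character vector (one or two factor names) defining the
#'   cells to compare.
#' @param adjust `"mvt"` (single-step multivariate), `"holm"`, or `"none"`.
#' @return data.frame: `contrast`, `estimate` (log scale), `se`, `z`,
#'   `p_value`, `p_adjusted`; inestimable contrasts carry `NA`.
#' @export
pairwise_contrasts <- function(fit, factors,
                               adjust = c("mvt", "holm", "none")) {
  adjust <- match.arg(adjust)
  if (!fit$converged)
    warning("contrasts computed from a fit flagged as not converged",
            call. = FALSE)
  if (is.null(fit$vcov)) stop("fit has no covariance matrix", call. = FALSE)
  lv <- fit_factor_levels(fit)
  if (!all(factors %in% names(lv)))
    stop("factors must name factor variables of the model", call. = FALSE)
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  mm <- stats::model.matrix(fit$fixed, grid)
  cell <- interaction(grid[factors], drop = FALSE, sep = " ")
  L <- do.call(rbind, lapply(split(seq_len(nrow(grid)), cell),
                             function(ix) colMeans(mm[ix, , drop = FALSE])))
  est <- drop(L %*% fit$coefficients)
  cells <- rownames(L)
  pairs <- utils::combn(length(cells), 2)
  C <- t(apply(pairs, 2, function(ij) L[ij[1], ] - L[ij[2], ]))
  d <- drop(C %*% fit$coefficients)
  V <- C %*% fit$vcov %*% t(C)
  se <- sqrt(pmax(diag(V), 0))
  se[se < 1e-12] <- NA                      # inestimable / degenerate cells
  z <- d / se
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- switch(adjust,
    none = p,
    holm = stats::p.adjust(p, "holm"),
    mvt = {
      ok <- is.finite(z)
      R <- stats::cov2cor(V[ok, ok, drop = FALSE])
      out <- rep(NA_real_, length(z))
      m <- nrow(R)
      out[ok] <- vapply(z[ok], function(zi)
        1 - mvtnorm::pmvnorm(lower = rep(-abs(zi), m),
                             upper = rep(abs(zi), m), sigma = R)[1], 0)
      pmin(pmax(out, p), 1)                 # never below the raw p
    })
  data.frame(contrast = apply(pairs, 2, function(ij)
    paste(cells[ij[1]], "-", cells[ij[2]])),
    estimate = d, se = se, z = z, p_value = p, p_adjusted = p_adj,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Parametric bootstrap confidence intervals for GLMM coefficients
#'
#' Simulates responses from the fitted model (new random intercepts plus
#' Poisson noise), refits, and takes percentile intervals of the refitted
#' coefficients. Failed or non-converged refits are dropped and counted;
#' more than 20% failures is an error.
#'
#' @param fit a converged `"callgram_glmm"`.
#' @param n_boot number of bootstrap refits.
#' @param seed optional seed for the simulation draws.
#' @param conf confidence level.
#' @return data.frame with `coefficient`, `estimate`, `lower`, `upper`;
#'   attribute `n_failed` counts dropped refits.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = NULL, conf = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate_glmm(fit, n_boot)
  draws <- matrix(NA_real_, n_boot, fit$npar_fixed)
  for (b in seq_len(n_boot)) {
    rf <- tryCatch(suppressWarnings(refit_newy(fit, sims[, b])),
                   error = function(e) NULL)
    if (!is.null(rf) && rf$converged && all(is.finite(rf$coefficients)))
      draws[b, ] <- rf$coefficients
  }
  ok <- stats::complete.cases(draws)
  if (mean(!ok) > 0.2)
    stop("more than 20% of bootstrap refits failed", call. = FALSE)
  a <- (1 - conf) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a))
  structure(data.frame(coefficient = names(fit$coefficients),
                       estimate = unname(fit$coefficients),
                       lower = qs[1, ], upper = qs[2, ], row.names = NULL),
            n_failed = sum(!ok))
}

#' Leave-one-group-out stability of GLMM estimates
#'
#' Refits the model once per grouping level with that level's rows removed
#' and reports the minimum and maximum of each fixed-effect estimate across
#' refits — the model-stability summary reported alongside coefficients.
#'
#' @param fit a `"callgram_glmm"` with at least three groups.
#' @return data.frame: `coefficient`, `estimate`, `min`, `max`.
#' @export
stability_analysis <- function(fit) {
  groups <- levels(fit$group)
  if (length(groups) < 3) stop("need at least 3 groups", call. = FALSE)
  est <- vapply(groups, function(gl) {
    tb <- fit$table[fit$table[[fit$group_column]] != gl, , drop = FALSE]
    rf <- suppressWarnings(
      fit_poisson_glmm(tb, fit$fixed, ridge_sd = fit$ridge_sd,
                       ridge_all = fit$ridge_all, response = fit$response,
                       offset_column = fit$offset_column,
                       group_column = fit$group_column, se = FALSE))
    rf$coefficients
  }, numeric(fit$npar_fixed))
  data.frame(coefficient = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             min = apply(est, 1, min), max = apply(est, 1, max),
             row.names = NULL)
}

#' Simulation-based dispersion check
#'
#' Compares the SD of the observed Pearson residuals (against the
#' conditional fitted means) with the SDs obtained from responses simulated
#' from those same fitted means. `ratio` > 1 indicates overdispersion,
#' < 1 underdispersion; the p-value is a two-sided simulation p with the
#' add-one convention.
#'
#' @param fit a `"callgram_glmm"`.
#' @param n_sim number of simulated response vectors.
#' @param seed optional seed.
#' @return list: `ratio`, `p_value`, `sd_observed`, `sd_simulated` (vector).
#' @export
dispersion_check <- function(fit, n_sim = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fit$fitted
  sd_obs <- stats::sd((fit$y - mu) / sqrt(pmax(mu, 1e-12)))
  sd_sim <- vapply(seq_len(n_sim), function(b) {
    ys <- stats::rpois(length(mu), mu)
    stats::sd((ys - mu) / sqrt(pmax(mu, 1e-12)))
  }, 0)
  denom <- max(mean(sd_sim), 1e-12)
  p_hi <- (1 + sum(sd_sim >= sd_obs)) / (n_sim + 1)
  p_lo <- (1 + sum(sd_sim <= sd_obs)) / (n_sim + 1)
  list(ratio = sd_obs / denom, p_value = min(1, 2 * min(p_hi, p_lo)),
       sd_observed = sd_obs, sd_simulated = sd_sim)
}
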