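# Poisson random-intercept GLMM, fitted by Laplace-approximate maximum
# likelihood: the per-group intercept modes are profiled out with a damped
# Newton solve (the inner problem is a one-dimensional convex root find per
# group, vectorized across groups), and the outer optimization over the fixed
# effects and log random-intercept SD uses a quasi-Newton method (nlminb).
# An optional zero-mean Gaussian ridge on the fixed effects (penalized
# likelihood) keeps estimates finite under complete separation.

# inner solve: for each group g find u_g with  yg = c_g e^u + u / s2
inner_modes <- function(cg, yg, inv_s2, u0 = NULL) {
  u <- if (is.null(u0)) rep(0, length(cg)) else u0
  for (it in 1:100) {
    Eu <- cg * exp(u)
    f <- Eu + u * inv_s2 - yg
    step <- f / (Eu + inv_s2)
    step <- pmax(pmin(step, 10), -10)
    u <- u - step
    if (max(abs(step)) < 1e-11) break
  }
  u
}

# negative penalized Laplace log-likelihood and its analytic gradient.
# The gradient accounts for the dependence of the conditional modes (and of
# the log-determinant correction) on the parameters: with per-group
# lambda_g = sum of conditional means and H_g = lambda_g + 1/sigma^2,
#   dL/dbeta_j = sum_i (y_i - mu_i) x_ij - (1/(2 sigma^2)) sum_g S_gj / H_g^2
#   dL/dlog(sigma) = sum_g u_g^2/sigma^2 - G + (1/sigma^2) sum_g (1 - lambda_g u_g)/H_g^2 ...
# (S_gj = sum_{i in g} mu_i x_ij; see the derivation in the methods vignette).
make_glmm_objective <- function(X, y, off, gi, G, pen_idx, ridge_sd) {
  ylg <- sum(lgamma(y + 1))
  yg <- as.numeric(rowsum(y, gi))
  p <- ncol(X)
  fn <- function(theta) {
    beta <- theta[seq_len(p)]
    sigma <- exp(theta[p + 1])
    inv_s2 <- 1 / sigma^2
    eta0 <- drop(X %*% beta) + off
    cg <- as.numeric(rowsum(exp(eta0), gi))
    u <- inner_modes(cg, yg, inv_s2)
    H <- cg * exp(u) + inv_s2
    ll <- sum(y * eta0) + sum(yg * u) - sum(cg * exp(u)) - ylg -
      sum(u^2) * inv_s2 / 2 - G * log(sigma) - 0.5 * sum(log(H))
    pen <- if (!is.null(ridge_sd))
      sum(beta[pen_idx]^2) / (2 * ridge_sd^2) else 0
    -ll + pen
  }
  gr <- function(theta) {
    beta <- theta[seq_len(p)]
    sigma <- exp(theta[p + 1])
    inv_s2 <- 1 / sigma^2
    eta0 <- drop(X %*% beta) + off
    w <- exp(eta0)
    cg <- as.numeric(rowsum(w, gi))
    u <- inner_modes(cg, yg, inv_s2)
    mu <- w * exp(u)[gi]
    lam <- cg * exp(u)
    H <- lam + inv_s2
    S <- rowsum(X * mu, gi)                       # G x p
    g_beta <- -drop(crossprod(X, y - mu)) +
      0.5 * inv_s2 * drop(crossprod(S, 1 / H^2))
    g_ls <- -(sum(u^2) * inv_s2 - G + inv_s2 * sum(1 / H) -
                inv_s2 * sum(lam * u / H^2))
    if (!is.null(ridge_sd))
      g_beta[pen_idx] <- g_beta[pen_idx] + beta[pen_idx] / ridge_sd^2
    c(g_beta, g_ls)
  }
  list(fn = fn, gr = gr)
}

#' Fit a Poisson random-intercept GLMM to a count table
#'
#' Fits `count ~ fixed effects + offset + (1 | group)` with Poisson errors
#' and log link by Laplace-approximate maximum likelihood. When `ridge_sd`
#' is set, independent zero-mean Gaussian priors with that SD are imposed on
#' the fixed effects as a penalized likelihood (intercept unpenalized unless
#' `ridge_all = TRUE`), which keeps estimates finite under complete or
#' quasi-complete separation — the situation where one predictor combination
#' has (near-)zero response variance.
#'
#' @param table data.frame with the response, predictors, an offset column
#'   and a grouping column (see [build_count_table()]).
#' @param fixed one-sided formula for the fixed effects, e.g.
#'   `~ level * stimulus + group_location`. Treatment coding with the factor
#'   level order of `table`.
#' @param ridge_sd SD of the Gaussian ridge, or `NULL` for no penalty.
#' @param ridge_all penalize the intercept too.
#' @param response,offset_column,group_column column names.
#' @param se compute standard errors (numerical Hessian at the optimum);
#'   refitting loops (bootstrap, stability) turn this off for speed.
#' @param sd_fixed fix the random-intercept SD at this value instead of
#'   estimating it (e.g. a value near zero recovers an ordinary Poisson GLM).
#' @return object of class `"callgram_glmm"` with elements `coefficients`,
#'   `se`, `vcov` (fixed effects), `sd_intercept`, `loglik` (unpenalized
#'   Laplace log-likelihood), `converged`, `u` (conditional modes), `fitted`
#'   (conditional means), `n_obs`, `n_groups`, plus the data needed for
#'   refits.
#' @seealso [lr_test()], [drop1_interactions()], [pairwise_contrasts()],
#'   [bootstrap_ci()], [stability_analysis()], [dispersion_check()]
#' @export
fit_poisson_glmm <- function(table, fixed, ridge_sd = NULL, ridge_all = FALSE,
                             response = "count", offset_column = "offset",
                             group_column = "trial_id", se = TRUE,
                             sd_fixed = NULL) {
  stopifnot(is.data.frame(table))
  for (col in c(response, group_column))
    if (!col %in% names(table)) stop("missing column: ", col, call. = FALSE)
  table <- droplevels(table)
  y <- table[[response]]
  if (any(y < 0) || any(y != floor(y))) stop("counts must be non-negative integers",
                                             call. = FALSE)
  off <- if (offset_column %in% names(table)) table[[offset_column]] else
    rep(0, nrow(table))
  g <- factor(table[[group_column]])
  gi <- as.integer(g)
  G <- nlevels(g)
  X <- stats::model.matrix(fixed, table)
  p <- ncol(X)
  if (qr(X)$rank < p && is.null(ridge_sd))
    stop("rank-deficient fixed-effect design; consider ridge_sd", call. = FALSE)
  pen_idx <- if (ridge_all) seq_len(p) else
    setdiff(seq_len(p), which(colnames(X) == "(Intercept)"))

  obj <- make_glmm_objective(X, y, off, gi, G, pen_idx, ridge_sd)

  start_beta <- tryCatch({
    b <- suppressWarnings(stats::glm.fit(X, y, offset = off,
                                         family = stats::poisson())$coefficients)
    b[!is.finite(b)] <- 0
    pmax(pmin(b, 3), -3)
  }, error = function(e) rep(0, p))
  ls_bounds <- if (is.null(sd_fixed)) log(c(1e-4, 100)) else
    rep(log(sd_fixed), 2)
  theta0 <- c(start_beta, if (is.null(sd_fixed)) log(0.5) else log(sd_fixed))

  fit <- stats::nlminb(theta0, obj$fn, gradient = obj$gr,
                       lower = c(rep(-Inf, p), ls_bounds[1]),
                       upper = c(rep(Inf, p), ls_bounds[2]),
                       control = list(iter.max = 500, eval.max = 1000))
  theta <- fit$par
  beta <- stats::setNames(theta[seq_len(p)], colnames(X))
  sigma <- as.numeric(exp(theta[p + 1]))

  vc <- NULL
  se_vec <- rep(NA_real_, p)
  converged <- fit$convergence == 0
  if (se) {
    hess <- if (is.null(sd_fixed)) {
      tryCatch(stats::optimHess(theta, obj$fn, obj$gr),
               error = function(e) NULL)
    } else {                                # curvature over beta only
      tryCatch(stats::optimHess(theta[seq_len(p)],
                                function(b) obj$fn(c(b, theta[p + 1])),
                                function(b) obj$gr(c(b, theta[p + 1]))[seq_len(p)]),
               error = function(e) NULL)
    }
    vc <- if (!is.null(hess))
      tryCatch(solve(hess), error = function(e) NULL) else NULL
    if (!is.null(vc) && all(diag(vc)[seq_len(p)] > 0))
      se_vec <- sqrt(diag(vc)[seq_len(p)])
    converged <- converged && all(is.finite(se_vec))
  }

  # conditional modes and fitted means at the optimum
  inv_s2 <- 1 / sigma^2
  eta0 <- drop(X %*% beta) + off
  cg <- as.numeric(rowsum(exp(eta0), gi))
  yg <- as.numeric(rowsum(y, gi))
  u <- inner_modes(cg, yg, inv_s2)
  ll <- as.numeric(-obj$fn(theta) + (if (!is.null(ridge_sd))
    sum(beta[pen_idx]^2) / (2 * ridge_sd^2) else 0))

  if (is.null(ridge_sd) && any(abs(beta) > 10))
    warning("|estimate| > 10 on the log scale: possible complete separation; ",
            "consider ridge_sd = 1", call. = FALSE)
  if (!converged)
    warning("GLMM fit did not converge cleanly", call. = FALSE)

  structure(list(
    coefficients = beta, se = stats::setNames(se_vec, colnames(X)),
    vcov = if (!is.null(vc)) vc[seq_len(p), seq_len(p), drop = FALSE] else NULL,
    sd_intercept = sigma, loglik = ll, converged = converged,
    u = stats::setNames(u, levels(g)),
    fitted = exp(eta0 + u[gi]),
    n_obs = length(y), n_groups = G, npar_fixed = p,
    ridge_sd = ridge_sd, ridge_all = ridge_all,
    fixed = fixed, table = table, response = response,
    offset_column = offset_column, group_column = group_column,
    X = X, y = y, offset = off, group = g),
    class = "callgram_glmm")
}

#' @export
print.callgram_glmm <- function(x, ...) {
  cat("Poisson random-intercept GLMM",
      if (!is.null(x$ridge_sd)) sprintf("(ridge sd %g)", x$ridge_sd), "\n")
  cat(deparse(x$fixed), "+ offset + (1 |", x$group_column, ")\n")
  print(round(data.frame(estimate = x$coefficients, se = x$se,
                         lower = x$coefficients - 1.96 * x$se,
                         upper = x$coefficients + 1.96 * x$se), 4))
  cat(sprintf("random-intercept SD %.4f | logLik %.3f | %d obs, %d groups\n",
              x$sd_intercept, x$loglik, x$n_obs, x$n_groups))
  if (!x$converged) cat("WARNING: fit flagged as not converged\n")
  invisible(x)
}

#' @export
logLik.callgram_glmm <- function(object, ...) {
  structure(object$loglik, df = object$npar_fixed + 1, class = "logLik")
}

#' @export
coef.callgram_glmm <- function(object, ...) object$coefficients

# refit the same data with a different fixed-effect formula (no SEs: the
# refits feed likelihood-ratio tests only)
refit_glmm <- function(fit, fixed, se = FALSE) {
  fit_poisson_glmm(fit$table, fixed, ridge_sd = fit$ridge_sd,
                   ridge_all = fit$ridge_all, response = fit$response,
                   offset_column = fit$offset_column,
                   group_column = fit$group_column, se = se)
}

# fast refit for a new response on the identical design (bootstrap loops):
# reuses the stored model matrix and warm-starts from the original optimum
refit_newy <- function(fit, ynew) {
  p <- fit$npar_fixed
  pen_idx <- if (fit$ridge_all) seq_len(p) else
    setdiff(seq_len(p), which(names(fit$coefficients) == "(Intercept)"))
  obj <- make_glmm_objective(fit$X, ynew, fit$offset,
                             as.integer(fit$group), fit$n_groups,
                             pen_idx, fit$ridge_sd)
  res <- stats::nlminb(c(fit$coefficients, log(fit$sd_intercept)),
                       obj$fn, gradient = obj$gr,
                       lower = c(rep(-Inf, p), log(1e-4)),
                       upper = c(rep(Inf, p), log(100)),
                       control = list(iter.max = 500, eval.max = 1000))
  list(coefficients = stats::setNames(res$par[seq_len(p)],
                                      names(fit$coefficients)),
       sd_intercept = exp(res$par[p + 1]),
       converged = res$convergence == 0)
}

# simulate response vectors from the fitted model (new intercepts + Poisson)
simulate_glmm <- function(fit, nsim = 1) {
  eta0 <- drop(fit$X %*% fit$coefficients) + fit$offset
  gi <- as.integer(fit$group)
  replicate(nsim, {
    u <- stats::rnorm(fit$n_groups, 0, fit$sd_intercept)
    stats::rpois(fit$n_obs, exp(eta0 + u[gi]))
  })
}

#' Likelihood-ratio test between nested GLMMs
#'
#' `chi2 = 2 * (ll_full - ll_reduced)` with degrees of freedom equal to the
#' difference in number of fixed-effect parameters, referred to the
#' chi-square upper tail. Both fits must be on the same data and offset.
#'
#' @param fit_full,fit_reduced `"callgram_glmm"` fits, reduced nested in
#'   full.
#' @return list: `chi2`, `df`, `p_value`.
#' @export
lr_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "callgram_glmm"),
            inherits(fit_reduced, "callgram_glmm"))
  if (fit_full$n_obs != fit_reduced$n_obs ||
      !isTRUE(all.equal(fit_full$y, fit_reduced$y)) ||
      !isTRUE(all.equal(fit_full$offset, fit_reduced$offset)))
    stop("fits are not on the same data/offset", call. = FALSE)
  if (!all(colnames(fit_reduced$X) %in% colnames(fit_full$X)))
    stop("reduced model is not nested in the full model", call. = FALSE)
  df <- fit_full$npar_fixed - fit_reduced$npar_fixed
  if (df < 0) stop("reduced model has more parameters than the full model",
                   call. = FALSE)
  chi2 <- max(2 * (fit_full$loglik - fit_reduced$loglik), 0)
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

# terms droppable under marginality: not contained in any other retained term
droppable_terms <- function(labels) {
  vars <- lapply(labels, function(l) strsplit(l, ":", fixed = TRUE)[[1]])
  keep <- vapply(seq_along(labels), function(i) {
    !any(vapply(seq_along(labels), function(j)
      j != i && all(vars[[i]] %in% vars[[j]]), TRUE))
  }, TRUE)
  labels[keep]
}

#' Per-term likelihood-ratio tests (drop one at a time)
#'
#' Tests each droppable fixed-effect term by refitting without it and
#' comparing by [lr_test()], respecting marginality: main effects involved in
#' an interaction are only tested after non-significant interactions (at
#' level `alpha`) have been removed from the model; those rows are flagged
#' `refitted`.
#'
#' @param fit a `"callgram_glmm"`.
#' @param alpha level below which an interaction is retained.
#' @return data.frame: `term`, `chi2`, `df`, `p_value`, `refitted`.
#' @export
drop1_interactions <- function(fit, alpha = 0.05) {
  labels <- attr(stats::terms(fit$fixed), "term.labels")
  test_against <- function(base_fit, base_labels, term, refitted) {
    reduced <- refit_glmm(base_fit,
                          if (length(setdiff(base_labels, term)))
                            stats::reformulate(setdiff(base_labels, term))
                          else ~1)
    t <- lr_test(base_fit, reduced)
    data.frame(term = term, chi2 = t$chi2, df = t$df, p_value = t$p_value,
               refitted = refitted, stringsAsFactors = FALSE)
  }
  first <- droppable_terms(labels)
  rows <- lapply(first, function(tm) test_against(fit, labels, tm, FALSE))
  res <- do.call(rbind, rows)
  # remove non-significant interactions, then test the newly droppable terms
  inter <- first[grepl(":", first)]
  drop_these <- inter[res$p_value[match(inter, res$term)] >= alpha]
  if (length(drop_these)) {
    labels2 <- setdiff(labels, drop_these)
    fit2 <- refit_glmm(fit, stats::reformulate(labels2))
    new_terms <- setdiff(droppable_terms(labels2), res$term)
    rows2 <- lapply(new_terms, function(tm)
      test_against(fit2, labels2, tm, TRUE))
    res <- rbind(res, do.call(rbind, rows2))
  }
  rownames(res) <- NULL
  res
}
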