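#' Deviance information criterion with effective parameter count
#'
#' The DIC is computed with level-1 (conditional) focus: the deviance is
#' \eqn{D(\theta, v) = -2 \log p(y \mid \theta, v)} with the random effects
#' treated as parameters, the plug-in deviance \eqn{\hat D} is evaluated at
#' the posterior means of all fixed effects, variance components, random
#' effects and imputed covariate values, and
#' \deqn{p_D = \bar{D} - \hat{D}, \qquad DIC = \bar{D} + p_D.}
#' A marginalized focus (random effects integrated out) is not currently
#' provided; the conditional focus matches the level-1 likelihood the
#' sampler records.
#'
#' @param fit A `bhpr_fit` (deviance draws are recorded at every kept draw).
#' @return A list with `dic`, `p_d` and `dev_mean`.
#' @seealso [dic_parts()] for the low-level computation from deviance draws.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "bhpr_fit"))
  dev <- unlist(fit$deviance)
  if (length(dev) == 0 || all(is.na(dev))) abort("No deviance draws stored.")
  pars_bar <- colMeans(posterior_matrix(fit))
  mu_hat <- model_mu(fit$model, pars_bar, fit$v_bar, fit$tvc_bar)
  dev_hat <- -2 * sum(dnorm(fit$model$y, mu_hat,
                            sqrt(pars_bar[["sigma2_e"]]), log = TRUE))
  dic_parts(dev, dev_hat)
}

#' DIC from deviance draws and a plug-in deviance
#'
#' @param dev_draws Numeric vector of per-draw deviances.
#' @param dev_hat Deviance at the posterior means.
#' @return A list with `dic`, `p_d`, `dev_mean`.
#' @export
dic_parts <- function(dev_draws, dev_hat) {
  dev_mean <- mean(dev_draws)
  p_d <- dev_mean - dev_hat
  list(dic = dev_mean + p_d, p_d = p_d, dev_mean = dev_mean)
}

#' Posterior predictive p-value
#'
#' For every kept draw, replicate responses are simulated from the fitted
#' model at that draw (conditional on its random effects) and a discrepancy
#' is computed identically for the replicated and the observed data; the
#' p-value is the fraction of draws in which the replicated discrepancy is
#' at least the observed one. The default discrepancy is the signed sum of
#' residuals \eqn{\sum_{ij} (y_{ij} - \hat y_{ij})}; a sum-of-squares
#' alternative is available. Values near 0.5 indicate an adequate model;
#' values near 0 or 1 indicate systematic misfit.
#'
#' @param fit A `bhpr_fit`.
#' @param seed Integer seed for the replicate simulation (results are
#'   reproducible given the seed).
#' @param statistic `"sum"` (signed sum of residuals, default) or `"sumsq"`.
#' @return The posterior predictive p-value in `[0, 1]`.
#' @export
posterior_predictive_pvalue <- function(fit, seed = 1,
                                        statistic = c("sum", "sumsq")) {
  stopifnot(inherits(fit, "bhpr_fit"))
  statistic <- match.arg(statistic)
  d_obs <- unlist(fit$resid_sum)
  sig <- sqrt(posterior_matrix(fit)[, "sigma2_e"])
  n <- fit$model$n
  set.seed(seed)
  if (statistic == "sum") {
    # replicate discrepancy: sum of iid N(0, sigma^2) residuals
    d_rep <- vapply(sig, function(s) sum(rnorm(n, 0, s)), numeric(1))
    mean(d_rep >= d_obs)
  } else {
    dev <- unlist(fit$deviance)
    # deviance = n log(2 pi sigma^2) + SSR / sigma^2, so invert for the SSR
    ssr_obs <- sig^2 * (dev - n * log(2 * pi * sig^2))
    d_rep <- vapply(sig, function(s) sum(rnorm(n, 0, s)^2), numeric(1))
    mean(d_rep >= ssr_obs)
  }
}

#' Significance of a group shift via its 95% credible interval
#'
#' A group effect on a trajectory parameter is called significant when the
#' central credible interval of its posterior excludes zero.
#'
#' @param fit A `bhpr_fit`.
#' @param which Parameter name: one of `"b0_grp"`, `"b1_grp"`, `"b2_grp"`,
#'   `"cp_grp"`.
#' @param level Credible level (default 0.95).
#' @return A list with `significant` (logical), `ci` (length-2 numeric) and
#'   `estimate` (posterior mean).
#' @export
group_effect_significant <- function(fit, which = "cp_grp", level = 0.95) {
  stopifnot(inherits(fit, "bhpr_fit"))
  draws <- posterior_matrix(fit)
  if (!which %in% colnames(draws)) {
    abort(paste0("`", which, "` is not free under divergence type `",
                 fit$model$divergence, "`."))
  }
  a <- (1 - level) / 2
  ci <- unname(quantile(draws[, which], c(a, 1 - a)))
  list(significant = ci[1] > 0 || ci[2] < 0, ci = ci,
       estimate = mean(draws[, which]))
}

#' Fit and compare the divergence-mechanism model suite
#'
#' Fits each requested candidate model (see [divergence_type()] for the
#' `A`-`H` labels) to the same dataset and compares them by DIC, with the
#' posterior predictive p-value as an adequacy check. The best model is the
#' converged fit with the lowest DIC, preferring fits whose posterior
#' predictive p-value lies in `[0.2, 0.8]`; exact ties go to the model with
#' fewer free group shifts.
#'
#' @param ds A [long_dataset()] tibble with a `group` column.
#' @param models Character vector of model letters or divergence-type names
#'   (at least 1).
#' @param priors A [prior_set()].
#' @param ranef,cov_structure,tic_terms,tvc_terms Passed to [bhpr_model()].
#' @param n_chains,n_burn,n_keep,thin,seed Passed to [bhpr_fit()].
#' @param rhat_limit Convergence threshold on the largest Gelman-Rubin
#'   statistic (multi-chain fits only).
#' @param keep_fits Keep the individual `bhpr_fit` objects in the result.
#' @return An object of class `bhpr_suite`: a list with `table` (one row per
#'   model: label, DIC, pD, PP p-value, max R-hat, convergence flag), `best`
#'   (the winning divergence type) and optionally `fits`.
#' @export
fit_divergence_suite <- function(ds, models = c("A", "E", "F"),
                                 priors = prior_set(), ranef = "b0",
                                 cov_structure = "independent",
                                 tic_terms = list(), tvc_terms = character(),
                                 n_chains = 2, n_burn = 5000, n_keep = 5000,
                                 thin = 5, seed = 1, rhat_limit = 1.1,
                                 keep_fits = FALSE) {
  if (length(models) < 1) abort("Give at least one candidate model.")
  types <- vapply(models, divergence_type, character(1))
  fits <- purrr::map(types, function(ty) {
    mod <- bhpr_model(ds, divergence = ty, ranef = ranef,
                      cov_structure = cov_structure,
                      tic_terms = tic_terms, tvc_terms = tvc_terms,
                      priors = priors)
    bhpr_fit(mod, n_chains = n_chains, n_burn = n_burn, n_keep = n_keep,
             thin = thin, seed = seed)
  })
  rows <- purrr::map2(types, fits, function(ty, ft) {
    ic <- compute_dic(ft)
    rh <- if (n_chains >= 2) max(gelman_rubin(ft)$rhat) else NA_real_
    conv <- is.na(rh) || rh <= rhat_limit
    tibble::tibble(
      model = names(MODEL_LETTERS)[match(ty, MODEL_LETTERS)] %||% NA_character_,
      divergence = ty, label = MODEL_LABELS[[ty]],
      dic = ic$dic, p_d = ic$p_d,
      pp_pvalue = posterior_predictive_pvalue(ft, seed = seed),
      max_rhat = rh, converged = conv,
      n_shifts = sum(DIVERGENCE_TYPES[[ty]])
    )
  })
  tab <- dplyr::bind_rows(rows)
  if (any(!tab$converged)) {
    warn(paste0("Excluded from best-model selection (R-hat > ", rhat_limit,
                "): ", paste(tab$divergence[!tab$converged], collapse = ", ")))
  }
  cand <- dplyr::filter(tab, .data$converged)
  if (nrow(cand) == 0) cand <- tab
  cand <- dplyr::arrange(cand,
                         !dplyr::between(.data$pp_pvalue, 0.2, 0.8),
                         .data$dic, .data$n_shifts)
  out <- list(table = tab, best = cand$divergence[1],
              fits = if (keep_fits) setNames(fits, types))
  class(out) <- "bhpr_suite"
  out
}

#' @export
print.bhpr_suite <- function(x, ...) {
  cat("<bhpr_suite> best model:", x$best, "\n")
  tab <- dplyr::mutate(x$table,
                       `DIC (pD)` = sprintf("%.0f (%.0f)", .data$dic, .data$p_d))
  print(dplyr::select(tab, "model", "label", "DIC (pD)", "pp_pvalue",
                      "converged"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bhpr_suite <- function(x, ...) x$table
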