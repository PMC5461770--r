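#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the split-chain \eqn{\widehat{R}} for every parameter: each chain
#' is split in half, and the classic between/within-chain variance ratio
#' \deqn{\widehat{R} = \sqrt{\frac{(n-1)/n \; W + B/n}{W}}}
#' is evaluated over the resulting `2 * n_chains` half-chains. Values near 1
#' indicate the chains have mixed; parameters with \eqn{\widehat{R} > 1.1}
#' are flagged.
#'
#' @param x A `bhpr_fit`, or a list of draw matrices (one per chain, equal
#'   dimensions, named columns).
#' @param split Split each chain in half first (recommended; detects
#'   within-chain drift).
#' @return A tibble with `term`, `rhat`, `flagged`.
#' @export
gelman_rubin <- function(x, split = TRUE) {
  chains <- if (inherits(x, "bhpr_fit")) x$draws else x
  if (!is.list(chains) || length(chains) < 2) {
    abort("Gelman-Rubin diagnostic needs at least 2 chains.")
  }
  n <- nrow(chains[[1]])
  if (n < 10) abort("Need at least 10 draws per chain.")
  if (split) {
    half <- n %/% 2
    chains <- purrr::flatten(purrr::map(chains, function(ch) {
      list(ch[seq_len(half), , drop = FALSE],
           ch[(nrow(ch) - half + 1):nrow(ch), , drop = FALSE])
    }))
  }
  n <- nrow(chains[[1]])
  terms <- colnames(chains[[1]])
  rhat <- purrr::map_dbl(setNames(terms, terms), function(tm) {
    xs <- vapply(chains, function(ch) ch[, tm], numeric(n))
    W <- mean(apply(xs, 2, var))
    B <- n * var(colMeans(xs))
    if (!is.finite(W) || W <= 0) return(1)
    # the (n-1)/n factor alone can push the ratio below 1; floor it there
    max(1, sqrt(((n - 1) / n * W + B / n) / W))
  })
  tibble::tibble(term = terms, rhat = unname(rhat),
                 flagged = unname(rhat) > 1.1)
}

#' @export
print.bhpr_fit <- function(x, ...) {
  cfg <- x$config
  cat("<bhpr_fit> divergence type:", x$model$divergence, "|",
      cfg$n_chains, "chain(s) x", nrow(x$draws[[1]]), "kept draws\n")
  print(summary(x), n = 15)
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object A `bhpr_fit`.
#' @param ... Unused.
#' @return A tibble with posterior mean, sd, central quantiles and (for
#'   multi-chain fits) the split-chain Gelman-Rubin statistic per parameter.
#' @export
summary.bhpr_fit <- function(object, ...) {
  all_draws <- posterior_matrix(object)
  qs <- t(apply(all_draws, 2, quantile, c(0.025, 0.5, 0.975)))
  out <- tibble::tibble(
    term = colnames(all_draws),
    mean = colMeans(all_draws),
    sd = apply(all_draws, 2, sd),
    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3]
  )
  if (length(object$draws) >= 2 && nrow(object$draws[[1]]) >= 10) {
    out$rhat <- gelman_rubin(object)$rhat
  }
  out
}

#' @rdname summary.bhpr_fit
#' @param x A `bhpr_fit`.
#' @exportS3Method generics::tidy
tidy.bhpr_fit <- function(x, ...) {
  out <- summary(x)
  dplyr::rename(out, estimate = "mean", std.error = "sd",
                conf.low = "q2.5", conf.high = "q97.5")
}

#' One-row model overview
#'
#' @param x A `bhpr_fit`.
#' @param ... Unused.
#' @return A tibble with data size, sampler settings, DIC, the effective
#'   number of parameters pD, and the largest Gelman-Rubin statistic.
#' @exportS3Method generics::glance
glance.bhpr_fit <- function(x, ...) {
  ic <- compute_dic(x)
  max_rhat <- if (length(x$draws) >= 2 && nrow(x$draws[[1]]) >= 10) {
    max(gelman_rubin(x)$rhat)
  } else NA_real_
  tibble::tibble(
    n_obs = x$model$n, n_subjects = x$model$m,
    divergence = x$model$divergence,
    n_chains = x$config$n_chains,
    n_draws = length(x$draws) * nrow(x$draws[[1]]),
    dic = ic$dic, p_d = ic$p_d, max_rhat = max_rhat
  )
}

#' Fitted values and residuals at the posterior means
#'
#' @param x A `bhpr_fit`.
#' @param ... Unused.
#' @return The model data with `.fitted` (posterior-mean fitted value,
#'   including random effects) and `.resid` columns.
#' @exportS3Method generics::augment
augment.bhpr_fit <- function(x, ...) {
  mu <- model_mu(x$model, colMeans(posterior_matrix(x)), x$v_bar, x$tvc_bar)
  out <- tibble::as_tibble(unclass_dataset(x$model$ds))
  out$.fitted <- mu
  out$.resid <- out$response - mu
  out
}

#' Export a fitted model's summaries as JSON
#'
#' Writes the posterior summary table, model description, DIC and sampler
#' configuration to a JSON file, for consumption outside R.
#'
#' @param fit A `bhpr_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  ic <- compute_dic(fit)
  out <- list(
    divergence = fit$model$divergence,
    n_obs = fit$model$n, n_subjects = fit$model$m,
    random_effects = fit$model$comps,
    cov_structure = fit$model$cov_structure,
    dic = ic$dic, p_d = ic$p_d,
    config = fit$config,
    summary = summary(fit)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Traceplots of the kept draws
#'
#' @param object A `bhpr_fit`.
#' @param pars Parameters to plot (default: fixed effects and variances, up
#'   to 12).
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter, coloured by chain.
#' @exportS3Method ggplot2::autoplot
autoplot.bhpr_fit <- function(object, pars = NULL, ...) {
  if (is.null(pars)) {
    pars <- head(colnames(object$draws[[1]]), 12)
  }
  df <- purrr::imap(object$draws, function(ch, i) {
    tibble::as_tibble(ch[, pars, drop = FALSE]) |>
      dplyr::mutate(.chain = factor(i), .iter = dplyr::row_number())
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_longer(dplyr::all_of(pars),
                        names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$.iter, .data$value,
                                   colour = .data$.chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "kept draw", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}
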