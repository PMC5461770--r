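#' Compare divergence-age estimators over simulated replicates
#'
#' For every scenario and replicate: simulate a dataset, fit the Type II
#' (change-point shift) hierarchical piecewise model and record the
#' posterior mean of the reference-group change point (the model's estimate
#' of the age at divergence), then fit the categorical mixed model and
#' record both LS-means read-outs ([earliest_significant_age()] and
#' [midway_divergence_age()]). Estimates are summarized per scenario and
#' method with [summarize_boxplot_stats()].
#'
#' The default replicate count and sampler protocol are deliberately short
#' (20 replicates; 2 chains, 5000 burn-in, 5000 kept, thinned by 5): they
#' give stable across-replicate averages at desk scale, and a full-length
#' protocol can be requested through `mcmc`.
#'
#' @param scenarios A named list of [sim_scenario()] objects (a single
#'   scenario is also accepted).
#' @param n_reps Replicates per scenario (>= 2).
#' @param methods Any of `"bhpr"`, `"earliest"`, `"midway"`.
#' @param mcmc Named list of sampler settings for the Type II fit:
#'   `n_chains`, `n_burn`, `n_keep`, `thin`.
#' @param ranef Random-effect components for the fitted model (default
#'   `"b0"`, matching the reference generator).
#' @param alpha Significance level for the LS-means read-outs.
#' @param seed Integer seed; replicate r of scenario s uses a seed derived
#'   from it.
#' @param progress Print one line per replicate to stderr.
#' @return An object of class `bhpr_simstudy`: `estimates` (scenario, rep,
#'   method, estimate, converged), `summary` (per scenario x method
#'   boxplot statistics), `truth` (generating divergence age per scenario),
#'   `n_failed` (replicates dropped per scenario).
#' @export
run_sim_study <- function(scenarios, n_reps = 20,
                          methods = c("bhpr", "earliest", "midway"),
                          mcmc = list(n_chains = 2, n_burn = 5000,
                                      n_keep = 5000, thin = 5),
                          ranef = "b0", alpha = 0.05, seed = 1,
                          progress = FALSE) {
  if (inherits(scenarios, "bhpr_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios))) {
    names(scenarios) <- purrr::map_chr(scenarios, function(sc) {
      paste0(sc$n_group1, "/", sc$n_group2)
    })
  }
  if (n_reps < 2) abort("`n_reps` must be >= 2.")
  methods <- match.arg(methods, several.ok = TRUE)

  rows <- list()
  n_failed <- setNames(integer(length(scenarios)), names(scenarios))
  for (s in seq_along(scenarios)) {
    sc <- scenarios[[s]]
    for (r in seq_len(n_reps)) {
      rep_seed <- (seed + 7919L * s + 131L * r) %% .Machine$integer.max
      ds <- simulate_dataset(sc, seed = rep_seed)
      est <- list()
      ok <- TRUE
      if ("bhpr" %in% methods) {
        ft <- tryCatch(
          bhpr_fit(bhpr_model(ds, divergence = "change_point", ranef = ranef),
                   n_chains = mcmc$n_chains %||% 2,
                   n_burn = mcmc$n_burn %||% 5000,
                   n_keep = mcmc$n_keep %||% 5000,
                   thin = mcmc$thin %||% 5, seed = rep_seed),
          error = function(e) e)
        if (inherits(ft, "error")) {
          ok <- FALSE
          message("replicate failed (", conditionMessage(ft), ")")
        } else {
          est$bhpr <- mean(posterior_matrix(ft)[, "cp"])
        }
      }
      if (any(c("earliest", "midway") %in% methods)) {
        ls <- tryCatch(
          suppressWarnings(fit_categorical_mixed(ds, alpha = alpha)),
          error = function(e) e)
        if (inherits(ls, "error")) {
          ok <- FALSE
          message("replicate failed (", conditionMessage(ls), ")")
        } else {
          if ("earliest" %in% methods) est$earliest <- ls$divergence_age_earliest
          if ("midway" %in% methods) est$midway <- ls$divergence_age_midway
        }
      }
      if (!ok) {
        n_failed[s] <- n_failed[s] + 1L
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        scenario = names(scenarios)[s], rep = r,
        method = names(est), estimate = unlist(est, use.names = FALSE)
      )
      if (progress) {
        message(sprintf("[%s] replicate %d/%d done",
                        names(scenarios)[s], r, n_reps))
      }
    }
  }
  estimates <- dplyr::bind_rows(rows)
  summ <- estimates |>
    dplyr::filter(is.finite(.data$estimate)) |>
    dplyr::group_by(.data$scenario, .data$method) |>
    dplyr::group_modify(~ summarize_boxplot_stats(.x$estimate)) |>
    dplyr::ungroup()
  out <- list(estimates = estimates, summary = summ,
              truth = purrr::map_dbl(scenarios, "cp"),
              n_failed = n_failed)
  class(out) <- "bhpr_simstudy"
  out
}

#' Five-number boxplot summary with whiskers
#'
#' Quartiles use linear interpolation (R's default type-7 convention); the
#' upper whisker is `min(max(x), Q3 + 1.5 * IQR)` and the lower whisker
#' `max(min(x), Q1 - 1.5 * IQR)`.
#'
#' @param x Numeric vector with at least one finite value.
#' @return A one-row tibble with `n`, `mean`, `min`, `q1`, `median`, `q3`,
#'   `max`, `iqr`, `whisker_lo`, `whisker_hi`.
#' @export
summarize_boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) abort("No finite values to summarize.")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  tibble::tibble(
    n = length(x), mean = mean(x), min = min(x),
    q1 = q[1], median = q[2], q3 = q[3], max = max(x), iqr = iqr,
    whisker_lo = max(min(x), q[1] - 1.5 * iqr),
    whisker_hi = min(max(x), q[3] + 1.5 * iqr)
  )
}

#' @export
print.bhpr_simstudy <- function(x, ...) {
  cat("<bhpr_simstudy>", dplyr::n_distinct(x$estimates$scenario),
      "scenario(s);", dplyr::n_distinct(x$estimates$rep), "replicates\n")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bhpr_simstudy <- function(x, ...) x$estimates

#' Boxplots of divergence-age estimates by scenario and method
#'
#' @param object A `bhpr_simstudy`.
#' @param ... Unused.
#' @return A ggplot: one box per method within each scenario, replicate
#'   means as open circles, and the generating divergence age as a dashed
#'   horizontal line.
#' @exportS3Method ggplot2::autoplot
autoplot.bhpr_simstudy <- function(object, ...) {
  df <- dplyr::filter(object$estimates, is.finite(.data$estimate))
  means <- df |>
    dplyr::group_by(.data$scenario, .data$method) |>
    dplyr::summarise(estimate = mean(.data$estimate), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$estimate)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_point(data = means, shape = 1, size = 3) +
    ggplot2::geom_hline(yintercept = unique(object$truth),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = NULL, y = "estimated age at divergence (years)") +
    ggplot2::theme_minimal()
}
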