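#' Categorical mixed model with per-age LS-means and group contrasts
#'
#' The traditional baseline for locating a divergence age: a linear mixed
#' model treating age as an unordered categorical factor,
#' `response ~ age_factor * group + (1 | subject)`, from which the estimated
#' marginal means (LS-means) of every age-by-group cell and the group
#' contrast at every age level are extracted. Contrast p-values are adjusted
#' for multiplicity over the family of per-age group contrasts with the
#' Tukey studentized-range adjustment ([tukey_pairwise()]).
#'
#' @param ds A [long_dataset()] tibble with a `group` column. Each distinct
#'   age value is used as a level; for ragged real data, supply `age_breaks`
#'   to bin ages first.
#' @param age_breaks Optional numeric break points passed to [cut()] to bin
#'   continuous ages into levels (labelled by the interval midpoints).
#' @param tvc_adjust Optional covariate columns added as fixed effects.
#' @param alpha Significance level used by the divergence-age read-outs.
#' @return An object of class `bhpr_lsmeans`: `means` (age, group, emmean,
#'   SE), `contrasts` (age, estimate, SE, t, p_value, p_adj), and the two
#'   divergence-age read-outs `divergence_age_earliest` and
#'   `divergence_age_midway` (years, `NA` when no level is significant).
#' @export
fit_categorical_mixed <- function(ds, age_breaks = NULL,
                                  tvc_adjust = character(), alpha = 0.05) {
  stopifnot(inherits(ds, "bhpr_data"))
  if (!"group" %in% names(ds)) abort("Dataset has no `group` column.")
  df <- tibble::as_tibble(unclass_dataset(ds))
  if (!is.null(age_breaks)) {
    mids <- (head(age_breaks, -1) + tail(age_breaks, -1)) / 2
    df$age_lvl <- mids[as.integer(cut(df$age, age_breaks))]
  } else {
    df$age_lvl <- df$age
  }
  df$age_f <- factor(df$age_lvl)
  df$group_f <- factor(df$group, levels = c(0, 1))
  if (dplyr::n_distinct(df$group_f) < 2) abort("Need both groups present.")

  # age levels observed in both groups; others are excluded from contrasts
  by_grp <- table(df$age_f, df$group_f)
  both <- rownames(by_grp)[apply(by_grp > 0, 1, all)]
  dropped <- setdiff(levels(df$age_f), both)
  if (length(dropped) > 0) {
    warn(paste0("Age level(s) present in only one group excluded from ",
                "contrasts: ", paste(dropped, collapse = ", ")))
  }

  form <- response ~ age_f * group_f + (1 | subject_id)
  if (length(tvc_adjust) > 0) {
    form <- stats::as.formula(paste(
      "response ~ age_f * group_f +",
      paste(tvc_adjust, collapse = " + "), "+ (1 | subject_id)"))
  }
  fit <- lme4::lmer(form, data = df,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  emm <- emmeans::emmeans(fit, ~ group_f | age_f, mode = "asymptotic")
  means <- tibble::as_tibble(summary(emm)) |>
    dplyr::transmute(age = as.numeric(as.character(.data$age_f)),
                     group = as.numeric(as.character(.data$group_f)),
                     emmean = .data$emmean, se = .data$SE) |>
    dplyr::arrange(.data$age, .data$group)
  ctr_raw <- tibble::as_tibble(
    summary(emmeans::contrast(emm, "revpairwise"), adjust = "none"))
  tcol <- intersect(c("t.ratio", "z.ratio"), names(ctr_raw))[1]
  ctr <- ctr_raw |>
    dplyr::transmute(age = as.numeric(as.character(.data$age_f)),
                     estimate = .data$estimate, se = .data$SE,
                     df = .data$df, t = .data[[tcol]],
                     p_value = .data$p.value) |>
    dplyr::filter(.data$age %in% as.numeric(both)) |>
    dplyr::arrange(.data$age)
  # large-sample df for the studentized-range adjustment
  df_resid <- nrow(df) - length(lme4::fixef(fit))
  ctr$p_adj <- tukey_pairwise(ctr$estimate, ctr$se, df = df_resid)

  out <- list(means = means, contrasts = ctr, alpha = alpha,
              model = fit)
  class(out) <- "bhpr_lsmeans"
  out$divergence_age_earliest <- earliest_significant_age(out, alpha)
  out$divergence_age_midway <- midway_divergence_age(out, alpha)
  out
}

#' @export
print.bhpr_lsmeans <- function(x, ...) {
  cat("<bhpr_lsmeans>", nrow(x$contrasts), "age-level group contrasts\n")
  cat("  earliest significant age:", x$divergence_age_earliest,
      "| midway divergence age:", x$divergence_age_midway, "\n")
  print(x$contrasts)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bhpr_lsmeans <- function(x, ...) x$contrasts

#' Tukey studentized-range adjustment for a family of contrasts
#'
#' Adjusts two-sided p-values of pairwise-difference contrasts using the
#' studentized range distribution: for contrast \eqn{t}-ratio \eqn{t_j},
#' \deqn{p_j = P\big(Q_{k,\nu} \ge \sqrt{2}\,|t_j|\big)}
#' where `k` is the number of cell means spanned by the family (twice the
#' number of per-age group contrasts) and \eqn{\nu} the residual degrees of
#' freedom. With a single contrast this reduces to the unadjusted two-sided
#' t-test.
#'
#' @param estimate Contrast estimates.
#' @param se Their standard errors.
#' @param df Residual degrees of freedom (may be `Inf`).
#' @param nmeans Number of means in the family; default `2 * length(estimate)`
#'   (each contrast is a difference of two cell means), with a minimum of 2.
#' @return Adjusted p-values in `[0, 1]`.
#' @export
tukey_pairwise <- function(estimate, se, df, nmeans = NULL) {
  if (length(estimate) != length(se)) abort("`estimate`/`se` length mismatch.")
  if (is.null(nmeans)) nmeans <- max(2, 2 * length(estimate))
  tval <- abs(estimate / se)
  ptukey(sqrt(2) * tval, nmeans = nmeans, df = df, lower.tail = FALSE)
}

lsmeans_pvalues <- function(lsres, alpha) {
  tab <- if (inherits(lsres, "bhpr_lsmeans")) lsres$contrasts
  else if (is.data.frame(lsres)) lsres
  else abort("`lsres` must be a bhpr_lsmeans object or a data frame with `age`, `p_adj`.")
  sig <- tab$p_adj < alpha
  sig[is.na(sig)] <- FALSE # non-estimable contrasts never count as significant
  list(age = tab$age, sig = sig)
}

#' Earliest age with a significant group difference
#'
#' The smallest age level at which the Tukey-adjusted group contrast is
#' significant — the traditional LS-means divergence-age read-out. By
#' definition it takes the first significant level even when surrounding
#' levels are not significant.
#'
#' @param lsres A `bhpr_lsmeans` object (or a data frame with columns `age`,
#'   `p_adj`).
#' @param alpha Significance level.
#' @return The age (years), or `NA` if no level is significant.
#' @export
earliest_significant_age <- function(lsres, alpha = 0.05) {
  pv <- lsmeans_pvalues(lsres, alpha)
  ord <- order(pv$age)
  hit <- pv$age[ord][pv$sig[ord]]
  if (length(hit) == 0) NA_real_ else hit[1]
}

#' Midway divergence age from LS-means contrasts
#'
#' Places a cut between two consecutive age levels so as to minimize the
#' number of misclassified levels (significant contrasts before the cut plus
#' non-significant contrasts after it) and returns the midpoint of the
#' optimal pair; ties go to the earliest cut. This read-out is less
#' sensitive than [earliest_significant_age()] to isolated significant
#' contrasts at young ages. When every level is significant the first age
#' level is returned; when none is, `NA`.
#'
#' @inheritParams earliest_significant_age
#' @return The midway age (years), or `NA`.
#' @export
midway_divergence_age <- function(lsres, alpha = 0.05) {
  pv <- lsmeans_pvalues(lsres, alpha)
  ord <- order(pv$age)
  ages <- pv$age[ord]
  sig <- pv$sig[ord]
  L <- length(ages)
  if (!any(sig)) return(NA_real_)
  if (all(sig)) return(ages[1])
  mis <- vapply(seq_len(L - 1), function(cut) {
    sum(sig[seq_len(cut)]) + sum(!sig[(cut + 1):L])
  }, numeric(1))
  best <- which.min(mis) # which.min takes the earliest on ties
  (ages[best] + ages[best + 1]) / 2
}

#' LS-means profile plot
#'
#' @param object A `bhpr_lsmeans` object.
#' @param ... Unused.
#' @return A ggplot of the estimated marginal means by age and group with
#'   the two divergence-age read-outs marked.
#' @exportS3Method ggplot2::autoplot
autoplot.bhpr_lsmeans <- function(object, ...) {
  ggplot2::ggplot(object$means,
                  ggplot2::aes(.data$age, .data$emmean,
                               colour = factor(.data$group))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$emmean - .data$se,
                                          ymax = .data$emmean + .data$se)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$divergence_age_earliest,
                        linetype = "dashed", na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$divergence_age_midway,
                        linetype = "dotted", na.rm = TRUE) +
    ggplot2::labs(x = "age (years)", y = "estimated marginal mean",
                  colour = "group") +
    ggplot2::theme_minimal()
}
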