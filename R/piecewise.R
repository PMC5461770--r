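#' Continuous broken-stick mean function
#'
#' Evaluates the two-phase linear ("broken-stick") mean curve
#' \deqn{\mu(age) = b_0 + b_1 (age - a_{ref}) + b_2 (age - cp)_+}{
#'       mu(age) = b0 + b1 (age - a_ref) + b2 max(age - cp, 0)}
#' which is continuous at the change point `cp`; the slope is `b1` before the
#' change point and `b1 + b2` after it, so `b2` is the change in slope, not
#' the post-change slope itself.
#'
#' @param age Numeric vector of ages (years, raw scale).
#' @param b0 Level at the reference age `a_ref` (response units).
#' @param b1 Slope before the change point (units/yr).
#' @param b2 Change in slope after the change point (units/yr).
#' @param cp Change point (years, raw age scale).
#' @param a_ref Reference age at which `b0` is the expected response.
#' @return Numeric vector of mean responses.
#' @export
#' @examples
#' piecewise_mean(c(16, 26), b0 = 10, b1 = 0.5, b2 = -0.3, cp = 16, a_ref = 0)
piecewise_mean <- function(age, b0, b1, b2, cp, a_ref = 0) {
  stopifnot(is.finite(cp))
  b0 + b1 * (age - a_ref) + b2 * pmax(age - cp, 0)
}

#' Gaussian log-likelihood of a hierarchical piecewise model state
#'
#' Sums the normal log-density of every observation at its subject-specific
#' piecewise mean. Subject trajectory parameters are the fixed effects plus
#' any group shifts, TIC contributions and random effects; TVC terms are
#' added directly to the level-1 mean. Missing TVC entries must already have
#' imputed values substituted.
#'
#' @param ds A [long_dataset()] tibble.
#' @param fixed Named list of fixed effects: `b0`, `b1`, `b2`, `cp`, optional
#'   group shifts `b0_grp`, `b1_grp`, `b2_grp`, `cp_grp`, optional named TIC
#'   coefficient lists `tic_b0` etc., optional named `tvc` coefficients.
#' @param sigma Residual standard deviation (> 0).
#' @param ranef Optional data frame of subject random effects with columns
#'   `subject_id` and any of `v0`, `v1`, `v2`, `v_cp` (defaults 0).
#' @return Scalar log-likelihood.
#' @export
piecewise_loglik <- function(ds, fixed, sigma, ranef = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  mu <- piecewise_mu(ds, fixed, ranef)
  sum(dnorm(ds$response, mu, sigma, log = TRUE))
}

# row-wise mean for a fixed/random state; reference implementation used by
# piecewise_loglik (the sampler keeps its own vectorized copy of this logic)
piecewise_mu <- function(ds, fixed, ranef = NULL) {
  a_ref <- attr(ds, "age_center")
  grp <- if ("group" %in% names(ds)) ds$group else rep(0, nrow(ds))
  g0 <- fixed$b0_grp %||% 0
  g1 <- fixed$b1_grp %||% 0
  g2 <- fixed$b2_grp %||% 0
  gcp <- fixed$cp_grp %||% 0
  b0 <- fixed$b0 + g0 * grp
  b1 <- fixed$b1 + g1 * grp
  b2 <- fixed$b2 + g2 * grp
  cp <- fixed$cp + gcp * grp
  for (p in c("b0", "b1", "b2", "cp")) {
    co <- fixed[[paste0("tic_", p)]]
    if (!is.null(co)) {
      for (v in names(co)) {
        add <- co[[v]] * ds[[v]]
        switch(p, b0 = b0 <- b0 + add, b1 = b1 <- b1 + add,
               b2 = b2 <- b2 + add, cp = cp <- cp + add)
      }
    }
  }
  if (!is.null(ranef)) {
    idx <- match(ds$subject_id, ranef$subject_id)
    b0 <- b0 + (ranef$v0 %||% rep(0, nrow(ranef)))[idx]
    b1 <- b1 + (ranef$v1 %||% rep(0, nrow(ranef)))[idx]
    b2 <- b2 + (ranef$v2 %||% rep(0, nrow(ranef)))[idx]
    cp <- cp + (ranef$v_cp %||% rep(0, nrow(ranef)))[idx]
  }
  mu <- b0 + b1 * (ds$age - a_ref) + b2 * pmax(ds$age - cp, 0)
  if (!is.null(fixed$tvc)) {
    for (v in names(fixed$tvc)) mu <- mu + fixed$tvc[[v]] * ds[[v]]
  }
  mu
}

#' Profile log-likelihood estimate of the population change point
#'
#' For each candidate change point on a grid, fits the two-slope fixed-effects
#' model `response ~ (age - a_ref) + (age - cp)_+` by least squares (random
#' effects omitted) and records the Gaussian profile log-likelihood. The
#' maximizing grid value (smallest on ties) is the profile-likelihood change
#' point, which is the recommended prior mean for the population change point
#' when fitting the full hierarchical model.
#'
#' @param ds A [long_dataset()] tibble.
#' @param cp_grid Candidate change points (years, raw scale). Default: steps
#'   of 0.5 yr spanning `[age_min + 2, age_max - 2]`, so both segments remain
#'   estimable at the ends of the grid.
#' @return A list with `cp_hat` (the maximizer), `flat` (`TRUE` when the
#'   profile is numerically constant, e.g. no slope change in the data), and
#'   `profile`, a tibble of (`cp`, `loglik`).
#' @export
profile_loglik_cp <- function(ds, cp_grid = NULL) {
  stopifnot(inherits(ds, "bhpr_data"))
  rng <- range(ds$age)
  if (is.null(cp_grid)) {
    cp_grid <- seq(rng[1] + 2, rng[2] - 2, by = 0.5)
  }
  if (any(cp_grid < rng[1] | cp_grid > rng[2])) {
    abort("`cp_grid` extends outside the observed age range.")
  }
  a_c <- ds$age - attr(ds, "age_center")
  n <- length(a_c)
  rss <- purrr::map_dbl(cp_grid, function(cp) {
    s <- pmax(ds$age - cp, 0)
    sum(residuals(lm(ds$response ~ a_c + s))^2)
  })
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  # no detectable slope change: the break never improves on a straight line
  rss_line <- sum(residuals(lm(ds$response ~ a_c))^2)
  tss <- sum((ds$response - mean(ds$response))^2)
  flat <- all((rss_line - rss) <= 1e-10 * max(tss, 1e-300))
  cp_hat <- cp_grid[which.max(ll)]
  if (flat) cp_hat <- min(cp_grid)
  list(cp_hat = cp_hat, flat = flat,
       profile = tibble::tibble(cp = cp_grid, loglik = ll))
}
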