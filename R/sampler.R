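#' Build a hierarchical piecewise model ready for sampling
#'
#' Assembles the parameter vector, design information, priors and initial
#' values for the Bayesian hierarchical piecewise regression model
#'
#' \deqn{y_{ij} \sim N(\mu_{ij}, \sigma^2_e), \quad
#'   \mu_{ij} = b_{0i} + b_{1i}(age_{ij} - a_{ref}) +
#'              b_{2i}(age_{ij} - CP_i)_+ + \sum_k \beta_{tvc,k} TVC_{ijk}}
#'
#' where each subject-level trajectory parameter is a population value plus
#' (optionally) a group shift, time-invariant-covariate contributions and a
#' random effect. The divergence type decides exactly which group shifts
#' (\eqn{\beta_{0grp}, \beta_{1grp}, \beta_{2grp}, \beta_{CP}}) are free; the
#' others are pinned to zero.
#'
#' Initial values are two-stage least squares: the change point from
#' [profile_loglik_cp()], segment slopes from the corresponding linear fit,
#' random effects at zero and variances at method-of-moments estimates.
#'
#' @param ds A [long_dataset()] tibble.
#' @param divergence Divergence type or model letter, see [divergence_type()].
#' @param ranef Character subset of `c("b0","b1","b2","cp")`: which trajectory
#'   parameters carry subject-level random effects.
#' @param cov_structure Covariance structure of the random effects:
#'   `"independent"` (mutually independent components), `"block_b1b2"`
#'   (non-zero correlation only between the two slope random effects, block
#'   diagonal otherwise), or `"full_unstructured"`.
#' @param tic_terms Named list mapping trajectory parameters (`b0`, `b1`,
#'   `b2`, `cp`) to character vectors of time-invariant covariates that act
#'   on them at level 2.
#' @param tvc_terms Character vector of time-varying covariates entering the
#'   level-1 mean directly; missing entries are imputed within the sampler
#'   under a normal missing-at-random model.
#' @param priors A [prior_set()].
#' @param init Named list overriding initial values (`b0`, `b1`, `b2`, `cp`,
#'   `sigma2_e`, ...).
#' @return An object of class `bhpr_model`.
#' @export
bhpr_model <- function(ds, divergence = "none", ranef = "b0",
                       cov_structure = c("independent", "block_b1b2",
                                         "full_unstructured"),
                       tic_terms = list(), tvc_terms = character(),
                       priors = prior_set(), init = list()) {
  stopifnot(inherits(ds, "bhpr_data"))
  cov_structure <- match.arg(cov_structure)
  divergence <- divergence_type(divergence)
  free <- free_group_shifts(divergence)

  n <- nrow(ds)
  subj_levels <- unique(ds$subject_id)
  m <- length(subj_levels)
  subj <- match(ds$subject_id, subj_levels)
  first_row <- match(subj_levels, ds$subject_id)

  if (any(free) && !"group" %in% names(ds)) {
    abort("This divergence type needs a `group` column in the dataset.")
  }
  grp_row <- if ("group" %in% names(ds)) as.numeric(ds$group) else numeric(n)
  grp_subj <- grp_row[first_row]

  comps <- intersect(c("b0", "b1", "b2", "cp"), ranef)
  if (length(setdiff(ranef, c("b0", "b1", "b2", "cp"))) > 0) {
    abort("`ranef` must be a subset of c(\"b0\",\"b1\",\"b2\",\"cp\").")
  }
  if (cov_structure == "block_b1b2" &&
      !all(c("b1", "b2") %in% comps)) {
    abort("`block_b1b2` needs both b1 and b2 random effects.")
  }

  bad_tic <- setdiff(names(tic_terms), c("b0", "b1", "b2", "cp"))
  if (length(bad_tic) > 0) {
    abort(paste0("Unknown trajectory parameter(s) in `tic_terms`: ",
                 paste(bad_tic, collapse = ", ")))
  }
  all_tic_vars <- unique(unlist(tic_terms, use.names = FALSE))
  miss <- setdiff(c(all_tic_vars, tvc_terms), names(ds))
  if (length(miss) > 0) {
    abort(paste0("Covariate column(s) not in dataset: ",
                 paste(miss, collapse = ", ")))
  }

  a_ref <- attr(ds, "age_center")
  age_c <- ds$age - a_ref

  # ---- linear-parameter layout ------------------------------------------
  lin_names <- "b0"
  if (free[["b0"]]) lin_names <- c(lin_names, "b0_grp")
  for (v in tic_terms$b0) lin_names <- c(lin_names, paste0("tic_b0_", v))
  lin_names <- c(lin_names, "b1")
  if (free[["b1"]]) lin_names <- c(lin_names, "b1_grp")
  for (v in tic_terms$b1) lin_names <- c(lin_names, paste0("tic_b1_", v))
  lin_names <- c(lin_names, "b2")
  if (free[["b2"]]) lin_names <- c(lin_names, "b2_grp")
  for (v in tic_terms$b2) lin_names <- c(lin_names, paste0("tic_b2_", v))
  for (v in tvc_terms) lin_names <- c(lin_names, paste0("tvc_", v))

  # change-point block (sampled by random-walk Metropolis)
  cp_names <- "cp"
  if (free[["cp"]]) cp_names <- c(cp_names, "cp_grp")
  for (v in tic_terms$cp) cp_names <- c(cp_names, paste0("tic_cp_", v))
  x_cp_subj <- if (length(tic_terms$cp) > 0) {
    as.matrix(ds[first_row, tic_terms$cp, drop = FALSE])
  } else {
    matrix(0, m, 0)
  }

  # static design columns (s-dependent ones are refreshed in the sampler)
  X <- matrix(0, n, length(lin_names), dimnames = list(NULL, lin_names))
  X[, "b0"] <- 1
  if (free[["b0"]]) X[, "b0_grp"] <- grp_row
  for (v in tic_terms$b0) X[, paste0("tic_b0_", v)] <- ds[[v]]
  X[, "b1"] <- age_c
  if (free[["b1"]]) X[, "b1_grp"] <- age_c * grp_row
  for (v in tic_terms$b1) X[, paste0("tic_b1_", v)] <- age_c * ds[[v]]
  s_cols <- c("b2", if (free[["b2"]]) "b2_grp",
              if (length(tic_terms$b2) > 0) paste0("tic_b2_", tic_terms$b2))
  s_parts <- list(rep(1, n))
  if (free[["b2"]]) s_parts <- c(s_parts, list(grp_row))
  if (length(tic_terms$b2) > 0) {
    s_parts <- c(s_parts, list(as.matrix(ds[, tic_terms$b2, drop = FALSE])))
  }
  s_mult <- do.call(cbind, s_parts)

  tvc_cols <- if (length(tvc_terms) > 0) paste0("tvc_", tvc_terms) else character()
  tvc_info <- purrr::map(setNames(tvc_terms, tvc_terms), function(v) {
    vals <- ds[[v]]
    miss_idx <- which(is.na(vals))
    if (length(miss_idx) == n && n > 0) {
      warn(paste0("TVC `", v, "` is entirely missing; its coefficient will ",
                  "track its prior."))
    }
    start <- vals
    start[miss_idx] <- mean(vals, na.rm = TRUE)
    if (all(is.na(vals))) start[] <- 0
    list(col = paste0("tvc_", v), miss = miss_idx, obs = vals[!is.na(vals)],
         start = start)
  })
  for (v in tvc_terms) X[, paste0("tvc_", v)] <- tvc_info[[v]]$start

  window <- attr(ds, "age_window")

  # ---- priors ------------------------------------------------------------
  pm <- prior_moments(priors, lin_names)
  cp_prior_mean <- setNames(numeric(length(cp_names)), cp_names)
  cp_prior_var <- setNames(rep(priors$beta_var[1], length(cp_names)), cp_names)
  profile <- NULL
  if (is.null(priors$cp_mean)) {
    if (n == 0) {
      abort("Empty dataset: supply `priors$cp_mean` (no data to profile).")
    }
    profile <- profile_loglik_cp(ds)
    cp_prior_mean["cp"] <- profile$cp_hat
  } else {
    cp_prior_mean["cp"] <- priors$cp_mean
  }
  cp_prior_var["cp"] <- priors$cp_var

  # ---- initial values ----------------------------------------------------
  st_init <- list()
  if (n > 0) {
    cp0 <- if (!is.null(profile)) profile$cp_hat else cp_prior_mean["cp"]
    s0 <- pmax(ds$age - cp0, 0)
    fit0 <- lm(ds$response ~ age_c + s0)
    cf <- coef(fit0)
    cf[is.na(cf)] <- 0
    st_init$beta <- setNames(numeric(length(lin_names)), lin_names)
    st_init$beta["b0"] <- cf[1]
    st_init$beta["b1"] <- cf[2]
    st_init$beta["b2"] <- cf[3]
    st_init$theta <- setNames(numeric(length(cp_names)), cp_names)
    st_init$theta["cp"] <- cp0
    res0 <- residuals(fit0)
    subj_mean_res <- tapply(res0, subj, mean)
    v_between <- max(var(as.numeric(subj_mean_res)), 0.01)
    st_init$sigma2 <- max(var(res0) - 0 , 0.05)
    if ("b0" %in% comps) st_init$sigma2 <- max(var(res0) - v_between, 0.05)
    st_init$phi_diag <- setNames(rep(0.1, length(comps)), comps)
    if ("b0" %in% comps) st_init$phi_diag["b0"] <- v_between
    if ("cp" %in% comps) st_init$phi_diag["cp"] <- 1
  } else {
    st_init$beta <- setNames(pm$mean, lin_names)
    st_init$theta <- cp_prior_mean
    st_init$sigma2 <- 1
    st_init$phi_diag <- setNames(rep(1, length(comps)), comps)
  }
  # user overrides
  for (p in intersect(names(init), c("b0", "b1", "b2"))) st_init$beta[p] <- init[[p]]
  for (p in intersect(names(init), lin_names)) st_init$beta[p] <- init[[p]]
  if ("cp" %in% names(init)) st_init$theta["cp"] <- init$cp
  for (p in intersect(names(init), cp_names)) st_init$theta[p] <- init[[p]]
  if ("sigma2_e" %in% names(init)) st_init$sigma2 <- init$sigma2_e

  structure(list(
    ds = ds, divergence = divergence, free = free,
    y = ds$response, age = ds$age, age_c = age_c, a_ref = a_ref,
    n = n, m = m, subj = subj, subj_levels = subj_levels,
    grp_row = grp_row, grp_subj = grp_subj,
    comps = comps, cov_structure = cov_structure,
    lin_names = lin_names, cp_names = cp_names,
    X = X, s_cols = s_cols, s_mult = s_mult,
    x_cp_subj = x_cp_subj, tvc_terms = tvc_terms, tvc_info = tvc_info,
    tic_terms = tic_terms, window = window,
    prior_mean = pm$mean, prior_var = pm$var,
    cp_prior_mean = cp_prior_mean, cp_prior_var = cp_prior_var,
    priors = priors, init = st_init, profile = profile
  ), class = "bhpr_model")
}

#' @export
print.bhpr_model <- function(x, ...) {
  cat("<bhpr_model> divergence type:", x$divergence,
      "|", x$m, "subjects,", x$n, "obs\n")
  cat("  fixed effects:", paste(c(x$lin_names, x$cp_names), collapse = ", "), "\n")
  cat("  random effects:", if (length(x$comps)) paste(x$comps, collapse = ", ")
      else "(none)", "-", x$cov_structure, "\n")
  invisible(x)
}

# number of free group-shift parameters (used for parsimony tie-breaks)
n_free_shifts <- function(model) sum(model$free)

# variance-parameter names for reporting
phi_par_names <- function(model) {
  comps <- model$comps
  out <- paste0("sigma2_v_", comps, recycle0 = TRUE)
  names(out) <- comps
  extra <- character()
  if (model$cov_structure == "block_b1b2") {
    extra <- "cov_v_b1_b2"
  } else if (model$cov_structure == "full_unstructured" && length(comps) > 1) {
    pr <- utils::combn(comps, 2)
    extra <- paste0("cov_v_", pr[1, ], "_", pr[2, ])
  }
  c(unname(out), extra)
}

#' Draw from the posterior of a hierarchical piecewise model
#'
#' Runs a Metropolis-within-Gibbs sampler: linear fixed effects (intercept,
#' slopes, group shifts on them, TIC and TVC coefficients) and random effects
#' on `b0`, `b1`, `b2` are updated with conjugate normal draws; variance
#' components with conjugate Inverse-Gamma (or inverse-Wishart for
#' correlated blocks); and every change-point parameter (population CP,
#' group CP shift, CP TIC coefficients and subject-level CP random effects)
#' with adaptive random-walk Metropolis tuned to an acceptance rate of 0.44
#' by Robbins-Monro scaling, frozen at the end of burn-in. Missing entries of
#' modelled time-varying covariates are imputed from their full conditional
#' each sweep; the TVC mean/precision hyperparameters are updated from the
#' observed entries only. Subject-level change points are constrained to the
#' declared observation window (population-CP proposals are reflected at the
#' boundary, subject-level proposals outside it are rejected).
#'
#' The deviance \eqn{-2 \log p(y \mid \theta, v)} (conditional on the random
#' effects) and the signed sum of residuals are recorded at every kept draw
#' for [compute_dic()] and [posterior_predictive_pvalue()].
#'
#' Defaults mirror a full-length analysis protocol (4 chains, 50000 burn-in,
#' 20000 post-burn-in iterations thinned by 10); simulation studies and tests
#' use much shorter, explicitly-passed runs.
#'
#' @param model A [bhpr_model()].
#' @param n_chains Number of independent chains (distinct seeds).
#' @param n_burn Burn-in iterations discarded per chain.
#' @param n_keep Post-burn-in iterations per chain; `n_keep / thin` draws are
#'   stored.
#' @param thin Thinning factor.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param store_ranef If `TRUE`, keep per-draw subject random effects (memory
#'   permitting); posterior means of the random effects are always stored.
#' @param jitter Scale of the random perturbation of each chain's initial
#'   values (0 starts all chains identically).
#' @return An object of class `bhpr_fit`.
#' @export
bhpr_fit <- function(model, n_chains = 4, n_burn = 50000, n_keep = 20000,
                     thin = 10, seed = 1, store_ranef = FALSE,
                     jitter = 0.1) {
  stopifnot(inherits(model, "bhpr_model"))
  if (n_chains < 1 || n_burn < 0 || n_keep < thin || thin < 1) {
    abort("Invalid sampler configuration.")
  }
  chains <- purrr::map(seq_len(n_chains), function(ch) {
    run_chain(model, n_burn = n_burn, n_keep = n_keep, thin = thin,
              seed = seed + ch - 1, store_ranef = store_ranef,
              jitter = jitter)
  })
  fit <- structure(list(
    model = model,
    draws = purrr::map(chains, "draws"),
    deviance = purrr::map(chains, "deviance"),
    resid_sum = purrr::map(chains, "resid_sum"),
    v_bar = Reduce(`+`, purrr::map(chains, "v_sum")) /
      max(1, n_chains * chains[[1]]$n_kept),
    tvc_bar = if (length(model$tvc_terms) > 0)
      purrr::map(setNames(model$tvc_terms, model$tvc_terms), function(v) {
        Reduce(`+`, purrr::map(chains, ~ .x$tvc_sum[[v]])) /
          max(1, n_chains * chains[[1]]$n_kept)
      }),
    v_draws = if (store_ranef) purrr::map(chains, "v_draws"),
    config = list(n_chains = n_chains, n_burn = n_burn, n_keep = n_keep,
                  thin = thin, seed = seed)
  ), class = "bhpr_fit")
  fit
}

# combined draws across chains
posterior_matrix <- function(fit) do.call(rbind, fit$draws)

# ---- the chain -------------------------------------------------------------

run_chain <- function(model, n_burn, n_keep, thin, seed, store_ranef,
                      jitter) {
  set.seed(seed)
  y <- model$y; n <- model$n; m <- model$m
  subj <- model$subj
  age <- model$age; age_c <- model$age_c
  grp_subj <- model$grp_subj
  X <- model$X
  lin_names <- model$lin_names
  p <- length(lin_names)
  s_idx <- match(model$s_cols, lin_names)
  s_mult <- model$s_mult
  comps <- model$comps
  d <- length(comps)
  has_vcp <- "cp" %in% comps
  lin_comps <- setdiff(comps, "cp")
  window <- model$window
  pr_mean <- model$prior_mean; pr_var <- model$prior_var
  cpn <- model$cp_names
  cp_pm <- model$cp_prior_mean; cp_pv <- model$cp_prior_var
  l1 <- model$priors$var_shape; l2 <- model$priors$var_rate
  tvc_terms <- model$tvc_terms

  # state
  beta <- model$init$beta
  theta <- model$init$theta
  sigma2 <- model$init$sigma2
  if (jitter > 0) {
    beta <- beta + rnorm(p, 0, jitter * (abs(beta) + 0.1))
    theta <- theta + rnorm(length(theta), 0, jitter)
    theta["cp"] <- min(max(theta["cp"], window[1]), window[2])
  }
  v <- matrix(0, m, d, dimnames = list(NULL, comps))
  phi <- diag(model$init$phi_diag[comps], d, d)
  dimnames(phi) <- list(comps, comps)
  tvc_mu <- setNames(rep(0, length(tvc_terms)), tvc_terms)
  tvc_tau <- setNames(rep(1, length(tvc_terms)), tvc_terms)
  tvc_val <- purrr::map(model$tvc_info, "start")
  for (tv in tvc_terms) {
    if (length(model$tvc_info[[tv]]$obs) > 0) {
      tvc_mu[tv] <- mean(model$tvc_info[[tv]]$obs)
      tvc_tau[tv] <- 1 / max(var(model$tvc_info[[tv]]$obs), 1e-6)
    }
  }

  # adaptive RWM steps
  step_theta <- setNames(rep(0.25, length(cpn)), cpn)
  step_vcp <- 1.0

  # subject change points and the s = (age - cp_i)+ basis
  subj_cp <- function(th, vcp) {
    out <- rep(th[["cp"]], m)
    if ("cp_grp" %in% cpn) out <- out + th[["cp_grp"]] * grp_subj
    if (ncol(model$x_cp_subj) > 0) {
      out <- out + drop(model$x_cp_subj %*%
                          th[paste0("tic_cp_", model$tic_terms$cp)])
    }
    if (has_vcp) out <- out + vcp
    out
  }
  vcp_cur <- if (has_vcp) v[, "cp"] else numeric(m)
  cp_i <- subj_cp(theta, vcp_cur)
  s <- pmax(age - cp_i[subj], 0)
  refresh_s_cols <- function() {
    X[, s_idx] <<- s_mult * s
  }
  refresh_s_cols()

  ranef_contrib <- function() {
    rv <- numeric(n)
    if ("b0" %in% comps) rv <- rv + v[subj, "b0"]
    if ("b1" %in% comps) rv <- rv + v[subj, "b1"] * age_c
    if ("b2" %in% comps) rv <- rv + v[subj, "b2"] * s
    rv
  }

  # blocks of linear random-effect components updated jointly
  lin_blocks <- switch(model$cov_structure,
    independent = as.list(lin_comps),
    block_b1b2 = c(if ("b0" %in% comps) list("b0"), list(c("b1", "b2"))),
    full_unstructured = if (length(lin_comps) > 0) list(lin_comps) else list()
  )

  phi_names <- phi_par_names(model)
  par_names <- c(lin_names, cpn, phi_names, "sigma2_e",
                 if (length(tvc_terms) > 0)
                   c(paste0("mu_tvc_", tvc_terms), paste0("sigma2_tvc_", tvc_terms)))
  n_kept <- n_keep %/% thin
  draws <- matrix(NA_real_, n_kept, length(par_names),
                  dimnames = list(NULL, par_names))
  dev_draws <- numeric(n_kept)
  rsum_draws <- numeric(n_kept)
  v_sum <- matrix(0, m, d, dimnames = list(NULL, comps))
  tvc_sum <- purrr::map(setNames(tvc_terms, tvc_terms),
                        ~ numeric(n))
  v_draws <- if (store_ranef) array(NA_real_, c(n_kept, m, d),
                                    dimnames = list(NULL, NULL, comps))

  acc_theta <- setNames(numeric(length(cpn)), cpn)

  total <- n_burn + n_keep
  Xb <- drop(X %*% beta)
  rv <- ranef_contrib()

  phi_entry <- function() {
    vals <- diag(phi)[comps]
    out <- vals
    if (model$cov_structure == "block_b1b2") {
      out <- c(out, phi["b1", "b2"])
    } else if (model$cov_structure == "full_unstructured" && d > 1) {
      pr <- utils::combn(comps, 2)
      out <- c(out, phi[cbind(pr[1, ], pr[2, ])])
    }
    out
  }

  # conditional prior of one block given the others (multivariate normal)
  cond_prior <- function(block) {
    rest <- setdiff(comps, block)
    Pbb <- phi[block, block, drop = FALSE]
    cross <- phi[block, rest, drop = FALSE]
    if (length(rest) == 0 || all(cross == 0)) {
      return(list(mean = matrix(0, m, length(block)),
                  cov = Pbb))
    }
    Prr_inv <- solve(phi[rest, rest, drop = FALSE])
    A <- cross %*% Prr_inv
    list(mean = v[, rest, drop = FALSE] %*% t(A),
         cov = Pbb - A %*% t(cross))
  }

  for (it in seq_len(total)) {
    in_burn <- it <= n_burn
    gam <- min(0.1, 2 / sqrt(it))

    ## ---- linear fixed effects (conjugate normal) -----------------------
    r <- y - rv
    XtX <- crossprod(X)
    Xtr <- drop(crossprod(X, r))
    A <- XtX / sigma2 + diag(1 / pr_var, p)
    b_ <- Xtr / sigma2 + pr_mean / pr_var
    ch <- chol(A)
    mean_beta <- backsolve(ch, backsolve(ch, b_, transpose = TRUE))
    beta <- setNames(mean_beta + backsolve(ch, rnorm(p)), lin_names)
    Xb <- drop(X %*% beta)

    ## ---- residual variance (conjugate Inverse-Gamma) -------------------
    res <- y - Xb - rv
    sigma2 <- 1 / rgamma(1, l1 + n / 2, l2 + sum(res^2) / 2)

    ## ---- linear random effects -----------------------------------------
    if (m > 0 && length(lin_blocks) > 0) {
      zcol <- function(comp) switch(comp, b0 = rep(1, n), b1 = age_c, b2 = s)
      for (block in lin_blocks) {
        pri <- cond_prior(block)
        if (length(block) == 1) {
          comp <- block[[1]]
          z <- zcol(comp)
          r0 <- y - Xb - (rv - v[subj, comp] * z)
          szz <- drop(rowsum(z * z, subj, reorder = TRUE))
          sz <- drop(rowsum(r0 * z, subj, reorder = TRUE))
          pvar <- pri$cov[1, 1]
          prec <- szz / sigma2 + 1 / pvar
          mu_v <- (sz / sigma2 + pri$mean[, 1] / pvar) / prec
          v[, comp] <- mu_v + rnorm(m) / sqrt(prec)
        } else {
          Z <- vapply(block, zcol, numeric(n))
          contrib <- rowSums(Z * v[subj, block, drop = FALSE])
          r0 <- y - Xb - (rv - contrib)
          P0 <- solve(pri$cov)
          for (i in seq_len(m)) {
            idx <- which(subj == i)
            Zi <- Z[idx, , drop = FALSE]
            Ai <- crossprod(Zi) / sigma2 + P0
            bi <- drop(crossprod(Zi, r0[idx])) / sigma2 +
              drop(P0 %*% pri$mean[i, ])
            chi <- chol(Ai)
            mui <- backsolve(chi, backsolve(chi, bi, transpose = TRUE))
            v[i, block] <- mui + backsolve(chi, rnorm(length(block)))
          }
        }
        rv <- ranef_contrib()
      }
    }

    ## ---- subject-level change points (vectorized RWM) -------------------
    if (has_vcp && m > 0) {
      c2_row <- drop(s_mult %*% beta[model$s_cols]) +
        if ("b2" %in% comps) v[subj, "b2"] else 0
      mu_cur <- Xb + rv
      base <- mu_cur - c2_row * s
      prop <- v[, "cp"] + step_vcp * rnorm(m)
      pri <- cond_prior("cp")
      cp_fix <- cp_i - v[, "cp"]
      cp_new <- cp_fix + prop
      ok <- cp_new >= window[1] & cp_new <= window[2]
      s_new <- pmax(age - cp_new[subj], 0)
      mu_new <- base + c2_row * s_new
      d_ssr <- drop(rowsum((y - mu_new)^2 - (y - mu_cur)^2, subj,
                           reorder = TRUE))
      pvar <- pri$cov[1, 1]
      logacc <- -d_ssr / (2 * sigma2) -
        ((prop - pri$mean[, 1])^2 - (v[, "cp"] - pri$mean[, 1])^2) / (2 * pvar)
      acc <- ok & (log(runif(m)) < logacc)
      v[acc, "cp"] <- prop[acc]
      if (in_burn) {
        step_vcp <- exp(log(step_vcp) + gam * (mean(acc) - 0.44))
      }
      vcp_cur <- v[, "cp"]
      cp_i <- cp_fix + vcp_cur
      s <- pmax(age - cp_i[subj], 0)
      refresh_s_cols()
      Xb <- drop(X %*% beta)
      rv <- ranef_contrib()
    }

    ## ---- random-effect covariance ---------------------------------------
    if (m > 0 && d > 0) {
      upd_ig <- function(comp) {
        1 / rgamma(1, l1 + m / 2, l2 + sum(v[, comp]^2) / 2)
      }
      if (model$cov_structure == "independent") {
        for (comp in comps) phi[comp, comp] <- upd_ig(comp)
      } else if (model$cov_structure == "block_b1b2") {
        for (comp in setdiff(comps, c("b1", "b2"))) {
          phi[comp, comp] <- upd_ig(comp)
        }
        Vb <- v[, c("b1", "b2"), drop = FALSE]
        S0 <- model$priors$iw_scale %||% diag(2)
        df0 <- model$priors$iw_df %||% 3
        Sn <- S0 + crossprod(Vb)
        W <- rWishart(1, df0 + m, solve(Sn))[, , 1]
        phi[c("b1", "b2"), c("b1", "b2")] <- solve(W)
      } else {
        S0 <- model$priors$iw_scale %||% diag(d)
        df0 <- model$priors$iw_df %||% (d + 1)
        Sn <- S0 + crossprod(v)
        W <- rWishart(1, df0 + m, solve(Sn))[, , 1]
        phi <- solve(W)
        dimnames(phi) <- list(comps, comps)
      }
    }

    ## ---- population change-point parameters (adaptive RWM) -------------
    c2_row <- drop(s_mult %*% beta[model$s_cols]) +
      if ("b2" %in% comps) v[subj, "b2"] else 0
    for (pn in cpn) {
      mu_cur <- Xb + rv
      base <- mu_cur - c2_row * s
      cur <- theta[[pn]]
      prop <- cur + step_theta[[pn]] * rnorm(1)
      if (pn == "cp") {
        # reflect at the observation window
        while (prop < window[1] || prop > window[2]) {
          if (prop < window[1]) prop <- 2 * window[1] - prop
          if (prop > window[2]) prop <- 2 * window[2] - prop
        }
      }
      th_new <- theta
      th_new[[pn]] <- prop
      cp_new <- subj_cp(th_new, vcp_cur)
      if (all(cp_new >= window[1] & cp_new <= window[2])) {
        s_new <- pmax(age - cp_new[subj], 0)
        mu_new <- base + c2_row * s_new
        logacc <- -(sum((y - mu_new)^2) - sum((y - mu_cur)^2)) / (2 * sigma2) -
          ((prop - cp_pm[[pn]])^2 - (cur - cp_pm[[pn]])^2) / (2 * cp_pv[[pn]])
        if (log(runif(1)) < logacc) {
          theta <- th_new
          cp_i <- cp_new
          s <- s_new
          refresh_s_cols()
          Xb <- drop(X %*% beta)
          rv <- ranef_contrib()
          acc_theta[[pn]] <- 1
        } else acc_theta[[pn]] <- 0
      } else acc_theta[[pn]] <- 0
      if (in_burn) {
        step_theta[[pn]] <- exp(log(step_theta[[pn]]) +
                                  gam * (acc_theta[[pn]] - 0.44))
      }
    }

    ## ---- TVC imputation and hyperparameters -----------------------------
    if (length(tvc_terms) > 0) {
      for (tv in tvc_terms) {
        info <- model$tvc_info[[tv]]
        bcoef <- beta[[info$col]]
        # hyperparameters from the observed part of the data only
        n_obs <- length(info$obs)
        if (n_obs > 0) {
          mu_prec <- n_obs * tvc_tau[[tv]] + 1 / model$priors$tvc_mu_var
          mu_mean <- (tvc_tau[[tv]] * sum(info$obs) +
                        model$priors$tvc_mu_mean / model$priors$tvc_mu_var) /
            mu_prec
          tvc_mu[tv] <- rnorm(1, mu_mean, 1 / sqrt(mu_prec))
          tvc_tau[tv] <- rgamma(1, model$priors$tvc_tau_shape + n_obs / 2,
                                model$priors$tvc_tau_rate +
                                  sum((info$obs - tvc_mu[[tv]])^2) / 2)
        } else {
          mu_prec <- 1 / model$priors$tvc_mu_var
          tvc_mu[tv] <- rnorm(1, model$priors$tvc_mu_mean, sqrt(model$priors$tvc_mu_var))
          tvc_tau[tv] <- rgamma(1, model$priors$tvc_tau_shape,
                                model$priors$tvc_tau_rate)
        }
        if (length(info$miss) > 0) {
          vals <- tvc_val[[tv]]
          mu_all <- Xb + rv
          r_part <- y[info$miss] - (mu_all[info$miss] - bcoef * vals[info$miss])
          prec <- tvc_tau[[tv]] + bcoef^2 / sigma2
          mean_t <- (tvc_tau[[tv]] * tvc_mu[[tv]] + bcoef * r_part / sigma2) / prec
          vals[info$miss] <- rnorm(length(info$miss), mean_t, 1 / sqrt(prec))
          tvc_val[[tv]] <- vals
          X[, info$col] <- vals
        }
      }
      Xb <- drop(X %*% beta)
    }

    ## ---- record ----------------------------------------------------------
    if (!in_burn && (it - n_burn) %% thin == 0) {
      k <- (it - n_burn) %/% thin
      mu_all <- Xb + rv
      draws[k, ] <- c(beta, theta, phi_entry(), sigma2,
                      if (length(tvc_terms) > 0)
                        c(tvc_mu, 1 / tvc_tau))
      dev_draws[k] <- -2 * sum(dnorm(y, mu_all, sqrt(sigma2), log = TRUE))
      rsum_draws[k] <- sum(y - mu_all)
      v_sum <- v_sum + v
      for (tv in tvc_terms) tvc_sum[[tv]] <- tvc_sum[[tv]] + tvc_val[[tv]]
      if (store_ranef) v_draws[k, , ] <- v
      if (has_vcp && m > 0 &&
          any(cp_i < window[1] - 1e-9 | cp_i > window[2] + 1e-9)) {
        abort("Internal error: subject change point left the age window.")
      }
    }
  }

  list(draws = draws, deviance = dev_draws, resid_sum = rsum_draws,
       v_sum = v_sum, tvc_sum = tvc_sum, v_draws = v_draws, n_kept = n_kept)
}

# ---- fitted-mean reconstruction -------------------------------------------

# mean vector at a named parameter vector `pars`, random effects `v`
# (m x d matrix, may be zero) and TVC values `tvc_vals`
model_mu <- function(model, pars, v = NULL, tvc_vals = NULL) {
  m <- model$m
  vcp <- if ("cp" %in% model$comps && !is.null(v)) v[, "cp"] else numeric(m)
  cp_i <- rep(pars[["cp"]], m)
  if ("cp_grp" %in% model$cp_names) cp_i <- cp_i + pars[["cp_grp"]] * model$grp_subj
  if (ncol(model$x_cp_subj) > 0) {
    cp_i <- cp_i + drop(model$x_cp_subj %*%
                          pars[paste0("tic_cp_", model$tic_terms$cp)])
  }
  cp_i <- cp_i + vcp
  s <- pmax(model$age - cp_i[model$subj], 0)
  X <- model$X
  X[, match(model$s_cols, model$lin_names)] <- model$s_mult * s
  for (tv in model$tvc_terms) {
    if (!is.null(tvc_vals[[tv]])) X[, model$tvc_info[[tv]]$col] <- tvc_vals[[tv]]
  }
  mu <- drop(X %*% pars[model$lin_names])
  if (!is.null(v)) {
    if ("b0" %in% model$comps) mu <- mu + v[model$subj, "b0"]
    if ("b1" %in% model$comps) mu <- mu + v[model$subj, "b1"] * model$age_c
    if ("b2" %in% model$comps) mu <- mu + v[model$subj, "b2"] * s
  }
  mu
}
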