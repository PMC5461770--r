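test_that("model building frees exactly the group shifts of the divergence type", {
  ds <- simulate_dataset(tiny_scenario(), seed = 1)
  m_e <- bhpr_model(ds, divergence = "change_point")
  expect_true("cp_grp" %in% m_e$cp_names)
  expect_false(any(c("b0_grp", "b1_grp", "b2_grp") %in% m_e$lin_names))

  m_h <- bhpr_model(ds, divergence = "all_four")
  expect_setequal(intersect(c("b0_grp", "b1_grp", "b2_grp"), m_h$lin_names),
                  c("b0_grp", "b1_grp", "b2_grp"))
  expect_true("cp_grp" %in% m_h$cp_names)

  # unconditional model has the same parameter count with or without groups
  m_a <- bhpr_model(ds, divergence = "none")
  ds_nogrp <- long_dataset(dplyr::select(tibble::as_tibble(ds), -"group"),
                           age_center = attr(ds, "age_center"))
  m_a2 <- bhpr_model(ds_nogrp, divergence = "none")
  expect_equal(length(m_a$lin_names) + length(m_a$cp_names),
               length(m_a2$lin_names) + length(m_a2$cp_names))

  expect_error(bhpr_model(ds_nogrp, divergence = "change_point"), "group")
})

test_that("identical seeds give bit-identical kept draws", {
  ds <- simulate_dataset(tiny_scenario(n1 = 10, n2 = 10), seed = 2)
  f1 <- quick_fit(ds, n_burn = 200, n_keep = 200, thin = 2, seed = 5)
  f2 <- quick_fit(ds, n_burn = 200, n_keep = 200, thin = 2, seed = 5)
  expect_identical(f1$draws, f2$draws)
  f3 <- quick_fit(ds, n_burn = 200, n_keep = 200, thin = 2, seed = 6)
  expect_false(identical(f1$draws, f3$draws))
  # draw count equals n_keep / thin per chain
  expect_equal(nrow(f1$draws[[1]]), 100)
})

test_that("near-noiseless data recover the generating fixed effects within 1%", {
  sc <- tiny_scenario(var_v0 = 0, var_e = 1e-4)
  ds <- simulate_dataset(sc, seed = 3)
  ft <- quick_fit(ds, ranef = character(), n_burn = 1500, n_keep = 1500,
                  thin = 3, seed = 1)
  est <- colMeans(posterior_matrix(ft))
  expect_equal(est[["b0"]], 24, tolerance = 0.01)
  expect_equal(est[["b1"]], 0.6, tolerance = 0.01)
  expect_equal(est[["b2"]], -0.45, tolerance = 0.01)
  expect_equal(est[["cp"]], 15, tolerance = 0.01)
  expect_equal(est[["cp_grp"]], 10, tolerance = 0.01)
})

test_that("a prior-only run reproduces the prior moments of a group shift", {
  empty <- long_dataset(
    data.frame(subject_id = character(), age = numeric(),
               response = numeric(), group = numeric()),
    group = "group", age_window = c(5, 50), age_center = 25)
  mod <- bhpr_model(empty, divergence = "intercept_only", ranef = character(),
                    priors = prior_set(cp_mean = 20))
  ft <- bhpr_fit(mod, n_chains = 2, n_burn = 200, n_keep = 4000, thin = 1,
                 seed = 4)
  draws <- posterior_matrix(ft)[, "b0_grp"]
  # prior is N(0, 1e4): sd 100
  expect_lt(abs(mean(draws)), 3 * 100 / sqrt(length(draws)) * 1.5 + 5)
  expect_equal(sd(draws), 100, tolerance = 0.1)
})

test_that("sigma^2 sweep leaves the analytic Inverse-Gamma posterior invariant", {
  # all other parameters pinned by (numerically) degenerate priors, no
  # random effects: sigma^2 | y is exactly Inverse-Gamma
  set.seed(10)
  df <- data.frame(id = 1, age = c(8, 12, 16, 20, 24, 28, 32, 36))
  b0 <- 20; b1 <- 0.5; b2 <- -0.3; cp <- 18; a_ref <- 20
  df$y <- b0 + b1 * (df$age - a_ref) + b2 * pmax(df$age - cp, 0) +
    rnorm(8, 0, 0.7)
  ds <- long_dataset(df, subject = "id", age = "age", response = "y",
                     age_center = a_ref)
  pin <- 1e-12
  pr <- prior_set(beta_mean = c(b0 = b0, b1 = b1, b2 = b2),
                  beta_var = c(b0 = pin, b1 = pin, b2 = pin),
                  cp_mean = cp, cp_var = pin,
                  var_shape = 2, var_rate = 1)
  mod <- bhpr_model(ds, divergence = "none", ranef = character(),
                    priors = pr, init = list(cp = cp))
  ft <- bhpr_fit(mod, n_chains = 1, n_burn = 100, n_keep = 5000, thin = 1,
                 seed = 2, jitter = 0)
  s2 <- posterior_matrix(ft)[, "sigma2_e"]
  mu <- b0 + b1 * (df$age - a_ref) + b2 * pmax(df$age - cp, 0)
  ssr <- sum((df$y - mu)^2)
  shape <- 2 + 8 / 2
  rate <- 1 + ssr / 2
  ks <- stats::ks.test(s2, function(q) {
    stats::pgamma(1 / q, shape, rate, lower.tail = FALSE)
  })
  expect_gt(ks$p.value, 0.01)
})

test_that("with change point pinned the posterior mean matches closed-form GLS", {
  # linear mixed model limit: cp pinned far right so the second segment is
  # never active; variances pinned by concentrated Inverse-Gamma priors
  set.seed(21)
  n_sub <- 30
  ages <- c(8, 14, 20, 26)
  # both variances pinned at 1 through a concentrated Inverse-Gamma prior
  sig2 <- 1; tau2 <- 1
  df <- data.frame(id = rep(seq_len(n_sub), each = 4),
                   age = rep(ages, n_sub))
  a_ref <- 17
  v0 <- rnorm(n_sub, 0, sqrt(tau2))
  df$y <- 21 + 0.4 * (df$age - a_ref) + v0[df$id] +
    rnorm(nrow(df), 0, sqrt(sig2))
  ds <- long_dataset(df, subject = "id", age = "age", response = "y",
                     age_center = a_ref, age_window = c(5, 60))
  conc <- 1e6
  pr <- prior_set(beta_mean = c(b2 = 0), beta_var = c(b2 = 1e-12),
                  cp_mean = 55, cp_var = 1e-12,
                  var_shape = conc, var_rate = (conc - 1) * 1)
  mod <- bhpr_model(ds, divergence = "none", ranef = "b0", priors = pr,
                    init = list(cp = 55))
  ft <- bhpr_fit(mod, n_chains = 2, n_burn = 500, n_keep = 4000, thin = 2,
                 seed = 3, jitter = 0)
  draws <- posterior_matrix(ft)
  # closed-form GLS posterior mean with known variances and vague beta prior
  X <- cbind(1, df$age - a_ref)
  Z <- model.matrix(~ 0 + factor(df$id))
  V <- diag(nrow(df)) * sig2 + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  P0 <- diag(1 / 1e4, 2)
  beta_gls <- solve(t(X) %*% Vi %*% X + P0, t(X) %*% Vi %*% df$y)
  for (k in 1:2) {
    est <- mean(draws[, c("b0", "b1")[k]])
    mcse <- sd(draws[, c("b0", "b1")[k]]) / sqrt(400) # conservative ESS
    expect_equal(est, beta_gls[k], tolerance = max(6 * mcse, 0.02),
                 ignore_attr = TRUE)
  }
})

test_that("posterior agrees with an independent general-purpose Gibbs sampler", {
  skip_if_not_installed("rjags")
  sc <- tiny_scenario(n1 = 25, n2 = 25, var_v0 = 1, var_e = 0.8)
  ds <- simulate_dataset(sc, seed = 12)
  mod <- bhpr_model(ds, divergence = "change_point", ranef = "b0")
  ft <- bhpr_fit(mod, n_chains = 2, n_burn = 3000, n_keep = 4000, thin = 2,
                 seed = 6)
  ours <- colMeans(posterior_matrix(ft))

  jags_code <- "
  model {
    for (k in 1:N) {
      cpi[k] <- cp + cpgrp * grp[k]
      mu[k] <- beta0 + v0[subj[k]] + beta1 * agec[k] +
               beta2 * (age[k] - cpi[k]) * step(age[k] - cpi[k])
      y[k] ~ dnorm(mu[k], tau_e)
    }
    for (i in 1:M) { v0[i] ~ dnorm(0, tau_v) }
    beta0 ~ dnorm(0, 1.0E-4)
    beta1 ~ dnorm(0, 1.0E-4)
    beta2 ~ dnorm(0, 1.0E-4)
    cp ~ dnorm(cp0, 1.0E-4)
    cpgrp ~ dnorm(0, 1.0E-4)
    tau_e ~ dgamma(0.001, 0.001)
    tau_v ~ dgamma(0.001, 0.001)
  }"
  subj <- match(ds$subject_id, unique(ds$subject_id))
  data <- list(N = nrow(ds), M = max(subj), y = ds$response,
               age = ds$age, agec = ds$age - attr(ds, "age_center"),
               grp = ds$group, subj = subj,
               cp0 = mod$cp_prior_mean[["cp"]])
  jm <- rjags::jags.model(textConnection(jags_code), data = data,
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 99))
  update(jm, 3000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("beta0", "beta1", "beta2", "cp", "cpgrp",
                                    "tau_e", "tau_v"),
                              n.iter = 4000, thin = 2,
                              progress.bar = "none")
  jpost <- colMeans(do.call(rbind, lapply(samp, as.matrix)))

  expect_equal(ours[["b0"]], jpost[["beta0"]], tolerance = 0.02)
  expect_equal(ours[["b1"]], jpost[["beta1"]], tolerance = 0.05)
  expect_equal(ours[["b2"]], jpost[["beta2"]], tolerance = 0.05)
  expect_equal(abs(ours[["cp"]] - jpost[["cp"]]), 0, tolerance = 0.3)
  expect_equal(abs(ours[["cp_grp"]] - jpost[["cpgrp"]]), 0, tolerance = 0.4)
  expect_equal(ours[["sigma2_e"]], 1 / jpost[["tau_e"]], tolerance = 0.1)
})

test_that("subject change points stay inside the observation window", {
  sc <- tiny_scenario(n1 = 15, n2 = 15, var_v0 = 1, var_e = 0.8)
  sc$var_cp <- 4
  ds <- simulate_dataset(sc, seed = 7)
  mod <- bhpr_model(ds, divergence = "change_point", ranef = c("b0", "cp"))
  ft <- bhpr_fit(mod, n_chains = 1, n_burn = 400, n_keep = 400, thin = 2,
                 seed = 8, store_ranef = TRUE)
  # the sampler asserts the window on every draw; also check the stored
  # posterior-mean subject effects imply in-window change points
  cps <- mean(posterior_matrix(ft)[, "cp"]) + ft$v_bar[, "cp"]
  w <- attr(ds, "age_window")
  expect_true(all(cps >= w[1] - 1 & cps <= w[2] + 1))
  expect_true(all(c("sigma2_v_b0", "sigma2_v_cp") %in%
                    colnames(ft$draws[[1]])))
})

test_that("correlated slope random effects run under the block structure", {
  sc <- tiny_scenario(n1 = 20, n2 = 20, var_v0 = 1, var_e = 0.6)
  sc$var_v1 <- 0.02
  sc$var_v2 <- 0.02
  ds <- simulate_dataset(sc, seed = 13)
  mod <- bhpr_model(ds, divergence = "change_point",
                    ranef = c("b0", "b1", "b2"),
                    cov_structure = "block_b1b2")
  ft <- bhpr_fit(mod, n_chains = 1, n_burn = 300, n_keep = 300, thin = 3,
                 seed = 9)
  draws <- posterior_matrix(ft)
  expect_true("cov_v_b1_b2" %in% colnames(draws))
  # covariance draws respect positive-definiteness of the 2x2 block
  expect_true(all(draws[, "sigma2_v_b1"] * draws[, "sigma2_v_b2"] >
                    draws[, "cov_v_b1_b2"]^2))
})

test_that("a modelled TVC with MAR missingness is recovered from partial data", {
  sc <- sim_scenario(40, 40, 24, 0.6, -0.45, 15, shifts = c(cp = 10),
                     var_v0 = 1, var_e = 0.8, a_ref = 25,
                     tvc = list(name = "ins", coef = 0.8, mean = 0, sd = 1,
                                miss_rate = 0.17))
  ds <- simulate_dataset(sc, seed = 31)
  expect_gt(mean(is.na(ds$ins)), 0.1)
  mod <- bhpr_model(ds, divergence = "change_point", ranef = "b0",
                    tvc_terms = "ins")
  ft <- bhpr_fit(mod, n_chains = 1, n_burn = 2000, n_keep = 2000, thin = 2,
                 seed = 3)
  sm <- summary(ft)
  est <- setNames(sm$mean, sm$term)
  sds <- setNames(sm$sd, sm$term)
  # coefficient recovered within 2 posterior sds despite ~17% missingness
  expect_lt(abs(est[["tvc_ins"]] - 0.8), 2 * sds[["tvc_ins"]])
  # TVC model hyperparameters track the generating normal(0, 1)
  expect_lt(abs(est[["mu_tvc_ins"]]), 0.2)
  expect_equal(est[["sigma2_tvc_ins"]], 1, tolerance = 0.25)
})

test_that("an entirely missing TVC warns and still yields a finite chain", {
  sc <- sim_scenario(15, 15, 24, 0.6, -0.45, 15, shifts = c(cp = 10),
                     var_v0 = 1, var_e = 0.8, a_ref = 25,
                     tvc = list(name = "ins", coef = 0.8, mean = 0, sd = 1,
                                miss_rate = 1))
  ds <- simulate_dataset(sc, seed = 32)
  expect_warning(
    mod <- bhpr_model(ds, divergence = "change_point", ranef = "b0",
                      tvc_terms = "ins"),
    "entirely missing")
  ft <- bhpr_fit(mod, n_chains = 1, n_burn = 500, n_keep = 500, thin = 2,
                 seed = 4)
  draws <- bhpr:::posterior_matrix(ft)
  expect_true(all(is.finite(draws[, "tvc_ins"])))
  # with no observed entries there is no real signal for the coefficient
  ci <- unname(quantile(draws[, "tvc_ins"], c(0.025, 0.975)))
  expect_lt(ci[1], 1)
  expect_gt(ci[2], -1)
})
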