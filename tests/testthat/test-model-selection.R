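test_that("DIC parts behave at a point-mass posterior and on a conjugate toy", {
  # all draws identical: no effective parameters
  parts <- dic_parts(rep(123.4, 50), 123.4)
  expect_equal(parts$p_d, 0)
  expect_equal(parts$dic, 123.4)

  # conjugate normal-mean model: one parameter => pD ~ 1
  set.seed(31)
  n <- 40; sigma <- 1
  y <- rnorm(n, 2, sigma)
  post_mean <- mean(y) / (1 + sigma^2 / (n * 100)) # vague N(0,100) prior
  post_sd <- sqrt(1 / (n / sigma^2 + 1 / 100))
  theta <- rnorm(1e4, post_mean, post_sd)
  dev <- vapply(theta, function(t) -2 * sum(dnorm(y, t, sigma, log = TRUE)),
                numeric(1))
  dev_hat <- -2 * sum(dnorm(y, mean(theta), sigma, log = TRUE))
  expect_equal(dic_parts(dev, dev_hat)$p_d, 1, tolerance = 0.1)
})

test_that("compute_dic matches a brute-force plug-in recomputation", {
  ds <- simulate_dataset(tiny_scenario(n1 = 12, n2 = 12), seed = 14)
  ft <- quick_fit(ds, n_burn = 400, n_keep = 400, thin = 2, seed = 2)
  got <- compute_dic(ft)

  draws <- posterior_matrix(ft)
  pars <- colMeans(draws)
  a_ref <- attr(ds, "age_center")
  cp_i <- pars[["cp"]] + pars[["cp_grp"]] * ft$model$grp_subj +
    ft$v_bar[, "b0"] * 0 # cp has no random effect here
  v0 <- ft$v_bar[, "b0"]
  subj <- ft$model$subj
  mu <- pars[["b0"]] + v0[subj] + pars[["b1"]] * (ds$age - a_ref) +
    pars[["b2"]] * pmax(ds$age - cp_i[subj], 0)
  dev_hat <- -2 * sum(dnorm(ds$response, mu, sqrt(pars[["sigma2_e"]]),
                            log = TRUE))
  dev_bar <- mean(unlist(ft$deviance))
  expect_equal(got$p_d, dev_bar - dev_hat, tolerance = 1e-8)
  expect_equal(got$dic, 2 * dev_bar - dev_hat, tolerance = 1e-8)
})

test_that("posterior predictive p-value is calibrated, directional and reproducible", {
  ds <- simulate_dataset(tiny_scenario(n1 = 15, n2 = 15), seed = 15)
  ft <- quick_fit(ds, n_burn = 600, n_keep = 600, thin = 2, seed = 3)
  p1 <- posterior_predictive_pvalue(ft, seed = 9)
  p2 <- posterior_predictive_pvalue(ft, seed = 9)
  expect_identical(p1, p2)
  expect_gt(p1, 0.05)
  expect_lt(p1, 0.95)

  # gross misfit: shift the observed data after freezing the fit
  ft_bad <- ft
  ft_bad$resid_sum <- purrr::map(ft$resid_sum, ~ .x + 10 * ft$model$n)
  p_bad <- posterior_predictive_pvalue(ft_bad, seed = 9)
  expect_gt(abs(p_bad - 0.5), 0.4)
})

test_that("group-effect significance reads the 95% credible interval", {
  ds <- simulate_dataset(tiny_scenario(n1 = 15, n2 = 15), seed = 16)
  ft <- quick_fit(ds, n_burn = 600, n_keep = 600, thin = 2, seed = 4)
  res <- group_effect_significant(ft, "cp_grp")
  expect_true(res$significant) # generating shift is 10 years
  expect_lt(res$ci[1], res$ci[2])
  expect_error(group_effect_significant(ft, "b1_grp"), "not free")

  # symmetric draws around zero are not significant
  ft2 <- ft
  ft2$draws <- purrr::map(ft$draws, function(m) {
    m[, "cp_grp"] <- rnorm(nrow(m))
    m
  })
  expect_false(group_effect_significant(ft2, "cp_grp")$significant)
})

test_that("the divergence suite prefers the generating Type II model", {
  ds <- simulate_dataset(tiny_scenario(n1 = 25, n2 = 25), seed = 17)
  suite <- fit_divergence_suite(ds, models = c("A", "E"),
                                n_chains = 2, n_burn = 2500, n_keep = 2000,
                                thin = 2, seed = 5)
  expect_s3_class(suite, "bhpr_suite")
  expect_equal(nrow(suite$table), 2)
  expect_equal(suite$best, "change_point")
  dic_a <- suite$table$dic[suite$table$divergence == "none"]
  dic_e <- suite$table$dic[suite$table$divergence == "change_point"]
  expect_lt(dic_e, dic_a)
  expect_true(all(suite$table$pp_pvalue >= 0 & suite$table$pp_pvalue <= 1))
  expect_equal(suite$table$label[suite$table$divergence == "none"],
               "Unconditional")
  expect_equal(suite$table$label[suite$table$divergence == "change_point"],
               "Group (change point CP)")

  one <- fit_divergence_suite(ds, models = "E", n_chains = 1, n_burn = 300,
                              n_keep = 300, thin = 3, seed = 6)
  expect_equal(one$best, "change_point")
})

test_that("gelman_rubin matches the textbook formula and flags separation", {
  set.seed(41)
  chains <- purrr::map(1:4, ~ matrix(rnorm(100), 100, 1,
                                     dimnames = list(NULL, "x")))
  got <- gelman_rubin(chains, split = FALSE)$rhat
  xs <- vapply(chains, function(ch) ch[, 1], numeric(100))
  W <- mean(apply(xs, 2, var))
  B <- 100 * var(colMeans(xs))
  oracle <- max(1, sqrt((99 / 100 * W + B / 100) / W))
  expect_equal(got, oracle, tolerance = 1e-10)

  # two identical chains: R-hat exactly 1
  same <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x"))
  expect_equal(gelman_rubin(list(same, same), split = FALSE)$rhat, 1,
               tolerance = 1e-12)

  # separated chains: R-hat far above 1
  apart <- list(matrix(rnorm(1000, 0), ncol = 1, dimnames = list(NULL, "x")),
                matrix(rnorm(1000, 5), ncol = 1, dimnames = list(NULL, "x")))
  expect_gt(gelman_rubin(apart)$rhat, 2)

  expect_error(gelman_rubin(list(same)), "2 chains")
})

test_that("prior sensitivity reports per-set DIC and is seed-stable", {
  ds <- simulate_dataset(tiny_scenario(n1 = 10, n2 = 10), seed = 18)
  sets <- list(a = prior_set(), b = prior_set(),
               c = prior_set(beta_var = 1e6))
  out <- run_prior_sensitivity(ds, sets, divergence = "change_point",
                               n_chains = 1, n_burn = 400, n_keep = 400,
                               thin = 2, seed = 7)
  expect_equal(nrow(out$dic), 3)
  # identical prior sets with identical seeds give identical summaries
  sa <- out$summaries[out$summaries$set == "a", ]
  sb <- out$summaries[out$summaries$set == "b", ]
  expect_equal(sa$mean, sb$mean)
  # vague-prior insensitivity: 1e4 vs 1e6 barely moves the posterior
  sc_ <- out$summaries[out$summaries$set == "c", ]
  expect_lt(max(abs(sa$mean - sc_$mean) /
                  pmax(sa$sd, 0.01)), 1.5)
  expect_error(run_prior_sensitivity(ds, sets["a"]), "at least 2")
})

test_that("fitted summaries export to JSON and read back consistently", {
  ds <- simulate_dataset(tiny_scenario(n1 = 8, n2 = 8), seed = 19)
  ft <- quick_fit(ds, n_burn = 200, n_keep = 200, thin = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(ft, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$divergence, "change_point")
  expect_equal(back$n_obs, nrow(ds))
  expect_equal(back$summary$mean,
               unname(summary(ft)$mean), tolerance = 1e-12)
  expect_equal(back$dic, compute_dic(ft)$dic, tolerance = 1e-9)
})
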