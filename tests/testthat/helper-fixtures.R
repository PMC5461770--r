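# shared fixtures: all built in code at test time

# small two-group piecewise dataset with a known truth
tiny_scenario <- function(n1 = 20, n2 = 20, var_v0 = 1, var_e = 0.5,
                          shifts = c(cp = 10)) {
  sim_scenario(n_group1 = n1, n_group2 = n2,
               b0 = 24, b1 = 0.6, b2 = -0.45, cp = 15,
               shifts = shifts, var_v0 = var_v0, var_e = var_e,
               baseline_ages = c(3, 6, 9, 12, 15, 18),
               offsets = c(3, 6, 9, 21, 27, 31), a_ref = 25)
}

# short-protocol fit used throughout the unit tests
quick_fit <- function(ds, divergence = "change_point", ranef = "b0",
                      n_chains = 1, n_burn = 1000, n_keep = 1000, thin = 2,
                      seed = 1, ...) {
  mod <- bhpr_model(ds, divergence = divergence, ranef = ranef, ...)
  bhpr_fit(mod, n_chains = n_chains, n_burn = n_burn, n_keep = n_keep,
           thin = thin, seed = seed)
}

# hand-built dataset (no simulator) for data-model tests
toy_long_df <- function() {
  data.frame(
    id = rep(c("a", "b", "c"), each = 3),
    age = rep(c(6, 9, 12), 3),
    y = c(15, 16, 17, 14.5, 15.5, 17.5, 16, 17, 18),
    grp = rep(c(0, 0, 1), each = 3)
  )
}
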