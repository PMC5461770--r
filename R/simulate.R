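#' Define a simulation scenario for an accelerated longitudinal design
#'
#' A scenario fixes the generating truth (piecewise trajectory parameters,
#' group shifts, variance components), the design (baseline-age pool and
#' follow-up offsets), and optionally a time-varying covariate model with
#' missing-at-random masking. Subjects are split into a reference group and
#' an index group whose trajectory parameters are shifted.
#'
#' @param n_group1,n_group2 Subjects in the reference / index group.
#' @param b0,b1,b2,cp Generating fixed effects: level at `a_ref`
#'   (response units), pre-change-point slope (units/yr), slope change after
#'   the change point (units/yr), change point (yr, raw age scale).
#' @param shifts Named numeric vector of index-group shifts on any of
#'   `b0`, `b1`, `b2`, `cp` (e.g. `c(cp = 12.37)` for a Type II divergence).
#' @param var_v0,var_v1,var_v2,var_cp Random-effect variances (0 disables a
#'   component).
#' @param ranef_cov Optional full covariance matrix of the non-zero
#'   random-effect components (overrides the individual variances'
#'   independence, not their inclusion).
#' @param var_e Residual (observation-level) variance.
#' @param baseline_ages Pool of baseline ages sampled uniformly per subject.
#' @param offsets Follow-up offsets (yr) added to the baseline age; the visit
#'   ages are `baseline + offsets`.
#' @param a_ref Reference (centering) age at which `b0` is the expected
#'   response.
#' @param tvc Optional list describing a normal time-varying covariate:
#'   `coef` (effect on the response), `mean`, `sd`, `miss_rate`
#'   (missing-at-random masking probability), `name`.
#' @return A list of class `bhpr_scenario`.
#' @export
sim_scenario <- function(n_group1, n_group2, b0, b1, b2, cp,
                         shifts = c(cp = 0),
                         var_v0 = 0, var_v1 = 0, var_v2 = 0, var_cp = 0,
                         ranef_cov = NULL, var_e = 1,
                         baseline_ages = c(3, 6, 9, 12, 15, 18),
                         offsets = c(3, 6, 9, 21, 27, 31),
                         a_ref = 25, tvc = NULL) {
  if (n_group1 <= 0 || n_group2 <= 0) abort("Group sizes must be > 0.")
  if (any(c(var_v0, var_v1, var_v2, var_cp, var_e) < 0)) {
    abort("Variances must be >= 0.")
  }
  if (is.unsorted(offsets, strictly = TRUE)) {
    abort("`offsets` must be strictly increasing.")
  }
  bad <- setdiff(names(shifts), c("b0", "b1", "b2", "cp"))
  if (length(bad) > 0) {
    abort(paste0("Unknown parameter(s) in `shifts`: ",
                 paste(bad, collapse = ", ")))
  }
  span <- range(baseline_ages) + range(offsets)[c(1, 2)]
  cp2 <- cp + (shifts[["cp"]] %||% 0)
  if (cp2 < span[1] || cp2 > span[2]) {
    warn("Index-group change point falls outside the design age span.")
  }
  structure(list(n_group1 = n_group1, n_group2 = n_group2,
                 b0 = b0, b1 = b1, b2 = b2, cp = cp, shifts = shifts,
                 var_v0 = var_v0, var_v1 = var_v1, var_v2 = var_v2,
                 var_cp = var_cp, ranef_cov = ranef_cov, var_e = var_e,
                 baseline_ages = baseline_ages, offsets = offsets,
                 a_ref = a_ref, tvc = tvc),
            class = "bhpr_scenario")
}

#' Built-in BMI-like Type II divergence scenario
#'
#' The reference simulation setting of the package: childhood-to-adulthood
#' BMI-like trajectories in which the index group (e.g. adults who develop
#' type 2 diabetes) reaches its change point 12.37 years later than the
#' reference group, with no other group difference (Type II divergence).
#' Generating values: intercept 26.5 kg/m2 at the reference age of 25 yr,
#' childhood slope 0.67 kg/m2/yr, slope change -0.49 kg/m2/yr, change point
#' 16.02 yr, participant-level random-intercept variance 2.77, residual
#' variance 2.47. The accelerated design draws baseline ages uniformly from
#' {3, 6, 9, 12, 15, 18} yr (six birth cohorts) with six repeated measures
#' 3, 6, 9, 21, 27 and 31 years later, so observed ages span 6-49 yr.
#'
#' @param n_group1,n_group2 Group sizes; the three reference sample-size
#'   scenarios are 100/100, 50/100 and 30/100.
#' @return A [sim_scenario()].
#' @export
bmi_divergence_scenario <- function(n_group1 = 100, n_group2 = 100) {
  sim_scenario(n_group1 = n_group1, n_group2 = n_group2,
               b0 = 26.5, b1 = 0.67, b2 = -0.49, cp = 16.02,
               shifts = c(cp = 12.37),
               var_v0 = 2.77, var_e = 2.47,
               baseline_ages = c(3, 6, 9, 12, 15, 18),
               offsets = c(3, 6, 9, 21, 27, 31), a_ref = 25)
}

scenario_ranef_comps <- function(sc) {
  vars <- c(b0 = sc$var_v0, b1 = sc$var_v1, b2 = sc$var_v2, cp = sc$var_cp)
  names(vars)[vars > 0]
}

#' Simulate a longitudinal dataset from a scenario
#'
#' Per subject: a baseline age is drawn uniformly from the scenario's pool,
#' visit ages are baseline + offsets, random effects are drawn from their
#' (co)variance, index-group subjects get the scenario's shifts added to
#' their trajectory parameters, and responses are the piecewise mean plus
#' random effects plus residual noise. An optional time-varying covariate is
#' generated and masked missing-at-random. The generating truth travels with
#' the dataset in its `truth` attribute; the subject's baseline age is kept
#' as a birth-cohort label.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Integer seed (identical scenario + seed gives an identical
#'   dataset).
#' @param cohort_effects Optional named list mapping trajectory parameters to
#'   named vectors of per-cohort shifts (cohort labels = baseline ages), see
#'   [simulate_cohort_shifts()].
#' @return A [long_dataset()] tibble with attribute `truth`.
#' @export
simulate_dataset <- function(scenario, seed = 1, cohort_effects = NULL) {
  stopifnot(inherits(scenario, "bhpr_scenario"))
  sc <- scenario
  set.seed(seed)
  n_sub <- sc$n_group1 + sc$n_group2
  grp <- rep(c(0, 1), c(sc$n_group1, sc$n_group2))
  baseline <- sample(sc$baseline_ages, n_sub, replace = TRUE)

  comps <- scenario_ranef_comps(sc)
  v <- matrix(0, n_sub, 4, dimnames = list(NULL, c("b0", "b1", "b2", "cp")))
  if (length(comps) > 0) {
    if (!is.null(sc$ranef_cov)) {
      if (!all(dim(sc$ranef_cov) == length(comps))) {
        abort("`ranef_cov` dimension must match the non-zero components.")
      }
      v[, comps] <- MASS::mvrnorm(n_sub, rep(0, length(comps)), sc$ranef_cov)
    } else {
      for (comp in comps) {
        v[, comp] <- rnorm(n_sub, 0, sqrt(switch(comp, b0 = sc$var_v0,
                                                 b1 = sc$var_v1,
                                                 b2 = sc$var_v2,
                                                 cp = sc$var_cp)))
      }
    }
  }

  par_subj <- cbind(b0 = sc$b0 + v[, "b0"], b1 = sc$b1 + v[, "b1"],
                    b2 = sc$b2 + v[, "b2"], cp = sc$cp + v[, "cp"])
  for (p in names(sc$shifts)) {
    par_subj[, p] <- par_subj[, p] + sc$shifts[[p]] * grp
  }
  if (!is.null(cohort_effects)) {
    bad <- setdiff(names(cohort_effects), c("b0", "b1", "b2", "cp"))
    if (length(bad) > 0) {
      abort(paste0("Unknown parameter(s) in `cohort_effects`: ",
                   paste(bad, collapse = ", ")))
    }
    for (p in names(cohort_effects)) {
      eff <- cohort_effects[[p]]
      hit <- match(as.character(baseline), names(eff))
      par_subj[, p] <- par_subj[, p] + ifelse(is.na(hit), 0, eff[hit])
    }
  }

  k <- length(sc$offsets)
  subj <- rep(seq_len(n_sub), each = k)
  age <- baseline[subj] + rep(sc$offsets, n_sub)
  mu <- piecewise_mean(age, par_subj[subj, "b0"], par_subj[subj, "b1"],
                       par_subj[subj, "b2"], par_subj[subj, "cp"],
                       a_ref = sc$a_ref)
  df <- tibble::tibble(
    subject_id = sprintf("S%04d", subj),
    age = age,
    group = grp[subj],
    cohort = as.character(baseline[subj]),
    response = mu + rnorm(length(age), 0, sqrt(sc$var_e))
  )

  tvcs <- character()
  if (!is.null(sc$tvc)) {
    nm <- sc$tvc$name %||% "tvc1"
    vals <- rnorm(nrow(df), sc$tvc$mean %||% 0, sc$tvc$sd %||% 1)
    df$response <- df$response + (sc$tvc$coef %||% 0) * vals
    miss <- runif(nrow(df)) < (sc$tvc$miss_rate %||% 0)
    vals[miss] <- NA_real_
    df[[nm]] <- vals
    tvcs <- nm
  }

  window <- range(sc$baseline_ages) + range(sc$offsets)[c(1, 2)]
  ds <- long_dataset(df, subject = "subject_id", age = "age",
                     response = "response", group = "group",
                     cohort = "cohort", tvcs = tvcs,
                     age_window = window, age_center = sc$a_ref)
  attr(ds, "truth") <- list(
    fixed = c(b0 = sc$b0, b1 = sc$b1, b2 = sc$b2, cp = sc$cp),
    shifts = sc$shifts,
    variances = c(var_v0 = sc$var_v0, var_v1 = sc$var_v1,
                  var_v2 = sc$var_v2, var_cp = sc$var_cp, var_e = sc$var_e),
    tvc = sc$tvc, scenario = sc, seed = seed,
    cohort_effects = cohort_effects
  )
  ds
}

#' Simulate with birth-cohort shifts on trajectory parameters
#'
#' Assigns each subject the birth cohort implied by its baseline age and
#' adds per-cohort shifts to the chosen trajectory parameters before
#' generating responses, emulating cohort effects in an accelerated
#' longitudinal design. With all shifts zero this is identical (same seed,
#' same draws) to [simulate_dataset()].
#'
#' @param scenario A [sim_scenario()].
#' @param cohort_effects Named list mapping trajectory parameters (`b0`,
#'   `b1`, `b2`, `cp`) to named numeric vectors of shifts keyed by cohort
#'   label (the baseline age as a character string); cohorts not named get 0.
#' @param seed Integer seed.
#' @return A [long_dataset()] tibble with attribute `truth`.
#' @export
simulate_cohort_shifts <- function(scenario, cohort_effects, seed = 1) {
  simulate_dataset(scenario, seed = seed, cohort_effects = cohort_effects)
}
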