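#' Prior hyperparameters for the hierarchical piecewise model
#'
#' Collects every prior used by [bhpr_model()]. Fixed effects (intercept,
#' slopes, group shifts, TIC and TVC coefficients) get independent normal
#' priors, vague by default (variance `1e4`) so the data dominate. The
#' population change point gets its own normal prior whose mean is, by
#' default, set at model-build time from the profile log-likelihood estimate
#' ([profile_loglik_cp()]); this anchors the random-walk updates in the
#' region the data support and shortens burn-in. Variances of independent
#' random-effect components and the residual variance get conjugate
#' Inverse-Gamma priors; correlated random-effect blocks get an
#' inverse-Wishart prior. The mean and precision of a normally-modelled
#' time-varying covariate with missing values get a vague normal and a
#' `Gamma(0.001, 0.001)` prior respectively.
#'
#' All normal priors are parameterized by mean and *variance* (not
#' precision).
#'
#' @param beta_mean,beta_var Mean and variance of the normal prior applied
#'   to each fixed effect. Either scalars or named vectors keyed by parameter
#'   name (e.g. `c(b1 = 0.5)`) to override individual parameters.
#' @param cp_mean Prior mean for the population change point (years); `NULL`
#'   means "use the profile log-likelihood estimate computed from the data".
#' @param cp_var Prior variance for the population change point.
#' @param var_shape,var_rate Inverse-Gamma shape/rate for variance
#'   components (random-effect variances and the residual variance).
#' @param iw_scale,iw_df Inverse-Wishart scale matrix and degrees of freedom
#'   for correlated random-effect blocks; `NULL` means identity scale and
#'   `dim + 1` degrees of freedom.
#' @param tvc_mu_mean,tvc_mu_var Normal prior on the mean of each modelled
#'   time-varying covariate.
#' @param tvc_tau_shape,tvc_tau_rate Gamma prior on its precision.
#' @return A list of class `bhpr_priors`.
#' @export
prior_set <- function(beta_mean = 0, beta_var = 1e4,
                      cp_mean = NULL, cp_var = 1e4,
                      var_shape = 0.001, var_rate = 0.001,
                      iw_scale = NULL, iw_df = NULL,
                      tvc_mu_mean = 0, tvc_mu_var = 1e4,
                      tvc_tau_shape = 0.001, tvc_tau_rate = 0.001) {
  if (any(beta_var <= 0) || cp_var <= 0 || tvc_mu_var <= 0) {
    abort("All prior variances must be > 0.")
  }
  if (var_shape <= 0 || var_rate <= 0 || tvc_tau_shape <= 0 ||
      tvc_tau_rate <= 0) {
    abort("Gamma/Inverse-Gamma prior parameters must be > 0.")
  }
  if (!is.null(iw_scale)) {
    if (!isSymmetric(unname(iw_scale)) ||
        any(eigen(iw_scale, only.values = TRUE)$values <= 0)) {
      abort("`iw_scale` must be symmetric positive definite.")
    }
    if (!is.null(iw_df) && iw_df < nrow(iw_scale) + 1) {
      abort("`iw_df` must be at least the block dimension + 1.")
    }
  }
  structure(list(beta_mean = beta_mean, beta_var = beta_var,
                 cp_mean = cp_mean, cp_var = cp_var,
                 var_shape = var_shape, var_rate = var_rate,
                 iw_scale = iw_scale, iw_df = iw_df,
                 tvc_mu_mean = tvc_mu_mean, tvc_mu_var = tvc_mu_var,
                 tvc_tau_shape = tvc_tau_shape, tvc_tau_rate = tvc_tau_rate),
            class = "bhpr_priors")
}

# prior mean/var vectors for a set of linear-parameter names
prior_moments <- function(priors, par_names) {
  pick <- function(x, nm, default) {
    out <- rep(if (length(x) == 1 && is.null(names(x))) x else default, length(nm))
    if (!is.null(names(x))) {
      hit <- intersect(names(x), nm)
      out[match(hit, nm)] <- x[hit]
    }
    out
  }
  list(mean = pick(priors$beta_mean, par_names, 0),
       var = pick(priors$beta_var, par_names, 1e4))
}

# ---- divergence-type bookkeeping -------------------------------------------

DIVERGENCE_TYPES <- list(
  none                     = c(b0 = FALSE, b1 = FALSE, b2 = FALSE, cp = FALSE),
  intercept_only           = c(b0 = TRUE,  b1 = FALSE, b2 = FALSE, cp = FALSE),
  childhood_slope          = c(b0 = FALSE, b1 = TRUE,  b2 = FALSE, cp = FALSE),
  adult_slope              = c(b0 = FALSE, b1 = FALSE, b2 = TRUE,  cp = FALSE),
  change_point             = c(b0 = FALSE, b1 = FALSE, b2 = FALSE, cp = TRUE),
  cp_and_adult_slope       = c(b0 = FALSE, b1 = FALSE, b2 = TRUE,  cp = TRUE),
  cp_childhood_adult_slopes = c(b0 = FALSE, b1 = TRUE, b2 = TRUE,  cp = TRUE),
  cp_and_intercept         = c(b0 = TRUE,  b1 = FALSE, b2 = FALSE, cp = TRUE),
  all_four                 = c(b0 = TRUE,  b1 = TRUE,  b2 = TRUE,  cp = TRUE)
)

MODEL_LETTERS <- c(A = "none", B = "intercept_only", C = "childhood_slope",
                   D = "adult_slope", E = "change_point",
                   F = "cp_and_adult_slope", G = "cp_childhood_adult_slopes",
                   H = "all_four")

MODEL_LABELS <- c(
  none = "Unconditional",
  intercept_only = "Group (intercept b0)",
  childhood_slope = "Group (childhood slope b1)",
  adult_slope = "Group (adulthood slope b2)",
  change_point = "Group (change point CP)",
  cp_and_adult_slope = "Group (CP + adulthood slope)",
  cp_childhood_adult_slopes = "Group (CP + childhood + adulthood slopes)",
  cp_and_intercept = "Group (intercept + CP)",
  all_four = "Group (all 4 parameters)")

#' Resolve a divergence-type name or model letter
#'
#' Candidate models are labelled `A` through `H`: `A` is the unconditional
#' model; `B`, `C`, `D` place the group shift on the intercept, childhood
#' slope or adulthood slope-change respectively; `E` shifts the change point
#' (Type II divergence); `F` shifts change point and adulthood slope
#' (Type III); `G` shifts change point and both slopes; `H` shifts all four
#' trajectory parameters. Full names (e.g. `"change_point"`,
#' `"cp_and_intercept"`) are also accepted.
#'
#' @param x A model letter or divergence-type name.
#' @return The canonical divergence-type name.
#' @export
divergence_type <- function(x) {
  x <- as.character(x)
  if (x %in% names(MODEL_LETTERS)) x <- MODEL_LETTERS[[x]]
  if (!x %in% names(DIVERGENCE_TYPES)) {
    abort(paste0("Unknown divergence type `", x, "`; use one of: ",
                 paste(names(DIVERGENCE_TYPES), collapse = ", "),
                 " or a model letter A-H."))
  }
  x
}

free_group_shifts <- function(divergence) DIVERGENCE_TYPES[[divergence_type(divergence)]]
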