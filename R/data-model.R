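#' Construct a validated long-format longitudinal dataset
#'
#' Takes one row per subject-visit and returns a validated tibble carrying the
#' metadata the modeling functions need: which columns are the subject id, age,
#' response and grouping factor, which are time-invariant (TIC) and
#' time-varying (TVC) covariates, the observation age window, and the age used
#' to center the time axis.
#'
#' @param data A data frame with one row per subject-visit.
#' @param subject,age,response Column names (strings) of the subject
#'   identifier, age in years, and continuous response.
#' @param group Optional column name of a binary group indicator (0 =
#'   reference, 1 = index group). Must be constant within subject.
#' @param cohort Optional column name of a categorical birth-cohort label.
#' @param tics Character vector of time-invariant covariate columns (constant
#'   within subject).
#' @param tvcs Character vector of time-varying covariate columns; missing
#'   values are allowed and recorded in an explicit mask.
#' @param age_window Length-2 numeric, the declared observation window
#'   `[age_min, age_max]`. Defaults to the observed age range.
#' @param age_center Reference age `a_ref` (years) used to center the time
#'   axis; the model intercept is the expected response at this age. Defaults
#'   to the grand mean of observed ages.
#'
#' @return A tibble of class `bhpr_data` with canonical columns `subject_id`,
#'   `age`, `response` (plus `group`, `cohort`, covariates and any extra
#'   columns, which are preserved but ignored by the models), and attributes
#'   `tics`, `tvcs`, `age_window`, `age_center`, `tvc_mask`.
#' @export
#' @examples
#' df <- data.frame(id = 1, age = c(6, 9, 12), y = c(15, 16, 17))
#' ds <- long_dataset(df, subject = "id", age = "age", response = "y")
#' attr(ds, "age_center")
long_dataset <- function(data, subject = "subject_id", age = "age",
                         response = "response", group = NULL, cohort = NULL,
                         tics = character(), tvcs = character(),
                         age_window = NULL, age_center = NULL) {
  data <- tibble::as_tibble(data)
  need <- c(subject, age, response, group, cohort, tics, tvcs)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Columns not found in `data`: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ren <- c(subject_id = subject, age = age, response = response)
  if (!is.null(group)) ren <- c(ren, group = group)
  if (!is.null(cohort)) ren <- c(ren, cohort = cohort)
  ds <- dplyr::rename(data, dplyr::all_of(ren))
  ds$subject_id <- as.character(ds$subject_id)

  if (anyNA(ds$age) || anyNA(ds$response)) {
    bad <- which(is.na(ds$age) | is.na(ds$response))
    abort(paste0("Missing age/response not allowed; offending rows: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (!is.numeric(ds$age) || !is.numeric(ds$response)) {
    abort("`age` and `response` must be numeric.")
  }
  if (is.null(age_window)) age_window <- range(ds$age)
  if (any(ds$age < age_window[1] | ds$age > age_window[2])) {
    abort("Ages outside the declared observation window.")
  }
  if (is.null(age_center)) age_center <- mean(ds$age)

  check_const <- c(if (!is.null(group)) "group", tics)
  for (v in check_const) {
    n_lvl <- tapply(ds[[v]], ds$subject_id, function(x) length(unique(x)))
    bad <- names(n_lvl)[n_lvl > 1]
    if (length(bad) > 0) {
      abort(paste0("`", v, "` is not constant within subject(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  if (!is.null(group)) {
    gl <- sort(unique(ds$group))
    if (!all(gl %in% c(0, 1))) {
      abort("`group` must be coded 0 (reference) / 1.")
    }
  }

  mask <- NULL
  if (length(tvcs) > 0) {
    mask <- purrr::map(setNames(tvcs, tvcs), ~ is.na(ds[[.x]]))
    mask <- tibble::as_tibble(mask)
  }

  structure(ds,
            tics = tics, tvcs = tvcs,
            age_window = as.numeric(age_window),
            age_center = as.numeric(age_center),
            tvc_mask = mask,
            class = c("bhpr_data", class(ds)))
}

#' @export
print.bhpr_data <- function(x, ...) {
  cat("<bhpr_data> ", dplyr::n_distinct(x$subject_id), " subjects, ",
      nrow(x), " observations; ages in [",
      paste(signif(attr(x, "age_window"), 4), collapse = ", "),
      "], centered at ", signif(attr(x, "age_center"), 4), "\n", sep = "")
  NextMethod()
}

# rebuild bhpr_data metadata after a transformation that kept the columns
rebuild_dataset <- function(ds, template, tics = attr(template, "tics"),
                            tvcs = attr(template, "tvcs")) {
  long_dataset(ds,
               subject = "subject_id", age = "age", response = "response",
               group = if ("group" %in% names(ds)) "group",
               cohort = if ("cohort" %in% names(ds)) "cohort",
               tics = tics, tvcs = tvcs,
               age_window = attr(template, "age_window"),
               age_center = attr(template, "age_center"))
}

#' Read a long-format longitudinal CSV
#'
#' Reads a comma-separated file (UTF-8, `.` decimal, empty cell or `NA` for
#' missing) and validates it with [long_dataset()]. The column map states
#' which columns play which role; it can be given inline or as a YAML file.
#'
#' @param path Path to the CSV file.
#' @param column_map A named list with entries `subject`, `age`, `response`
#'   and optionally `group`, `cohort`, `tics`, `tvcs`, `age_window`,
#'   `age_center`; or the path to a YAML file with those keys.
#' @return A validated [long_dataset()] tibble.
#' @export
read_long_csv <- function(path, column_map) {
  if (is.character(column_map) && length(column_map) == 1) {
    column_map <- yaml::read_yaml(column_map)
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
  long_dataset(raw,
               subject = column_map$subject %||% "subject_id",
               age = column_map$age %||% "age",
               response = column_map$response %||% "response",
               group = column_map$group,
               cohort = column_map$cohort,
               tics = as.character(column_map$tics %||% character()),
               tvcs = as.character(column_map$tvcs %||% character()),
               age_window = column_map$age_window,
               age_center = column_map$age_center)
}

#' Write a longitudinal dataset to CSV
#'
#' Writes the data columns (not the attributes) as a plain CSV that
#' [read_long_csv()] round-trips exactly: UTF-8, `.` decimal, `NA` for
#' missing values, full double precision.
#'
#' @param ds A [long_dataset()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(unclass_dataset(ds)), path, na = "NA")
  invisible(path)
}

unclass_dataset <- function(ds) {
  class(ds) <- setdiff(class(ds), "bhpr_data")
  ds
}

#' Standardize (and optionally log-transform) covariates
#'
#' Centers and scales the requested covariates to mean 0 and standard
#' deviation 1 over their non-missing entries, after an optional log
#' transform. Standardizing time-varying covariates stabilizes the variance
#' and improves the normality of errors; log-transforming right-skewed
#' covariates (such as fasting insulin) linearizes their relation to the
#' response. The transform parameters are stored for back-mapping.
#'
#' @param ds A [long_dataset()] tibble.
#' @param vars Covariate columns to standardize; defaults to all TVCs.
#' @param log_first Subset of `vars` to log-transform before standardizing.
#' @return The dataset with transformed columns and a `standardization`
#'   attribute (a tibble with `variable`, `log`, `center`, `scale`).
#' @export
standardize_covariates <- function(ds, vars = attr(ds, "tvcs"),
                                   log_first = character()) {
  stopifnot(inherits(ds, "bhpr_data"))
  if (!all(log_first %in% vars)) abort("`log_first` must be a subset of `vars`.")
  params <- purrr::map(vars, function(v) {
    x <- ds[[v]]
    if (!is.numeric(x)) abort(paste0("`", v, "` is not numeric."))
    if (v %in% log_first) {
      if (any(x <= 0, na.rm = TRUE)) {
        abort(paste0("`", v, "` has non-positive values; cannot log-transform."))
      }
      x <- log(x)
    }
    ctr <- mean(x, na.rm = TRUE)
    scl <- sd(x, na.rm = TRUE)
    if (!is.finite(scl) || scl == 0) {
      abort(paste0("`", v, "` has zero variance; cannot standardize."))
    }
    ds[[v]] <<- (x - ctr) / scl
    tibble::tibble(variable = v, log = v %in% log_first,
                   center = ctr, scale = scl)
  })
  out <- rebuild_dataset(ds, ds)
  attr(out, "standardization") <- dplyr::bind_rows(params)
  out
}

#' Expand the cohort label into k-1 indicator covariates
#'
#' For a cohort factor with `k` levels, appends `k - 1` binary dummy
#' variables (reference level all-zero) and registers them as time-invariant
#' covariates, so that cohort membership can sequentially shift the
#' conditional means of the trajectory parameters at level 2.
#'
#' @param ds A [long_dataset()] tibble with a `cohort` column.
#' @param reference_level Cohort level coded as all-zero.
#' @return The dataset with `cohort_<level>` indicator columns added to the
#'   TIC set.
#' @export
make_cohort_dummies <- function(ds, reference_level) {
  stopifnot(inherits(ds, "bhpr_data"))
  if (!"cohort" %in% names(ds)) abort("Dataset has no `cohort` column.")
  lvls <- sort(unique(as.character(ds$cohort)))
  if (length(lvls) < 2) abort("`cohort` must have at least 2 levels.")
  reference_level <- as.character(reference_level)
  if (!reference_level %in% lvls) {
    abort(paste0("Reference level `", reference_level, "` absent from cohort."))
  }
  others <- setdiff(lvls, reference_level)
  dnames <- paste0("cohort_", others)
  for (i in seq_along(others)) {
    ds[[dnames[i]]] <- as.numeric(as.character(ds$cohort) == others[i])
  }
  rebuild_dataset(ds, ds, tics = union(attr(ds, "tics"), dnames))
}
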