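#' Heat-experience count outcome
#'
#' The number of "yes" answers over the 11 heat-related symptom items
#' (sweating or clammy skin; dry or red skin; muscle cramps; headache;
#' dizziness; nausea; weakness or fatigue; confusion; palpitations; chest
#' pain; shortness of breath), taking values 0-11. Any missing item makes
#' the outcome missing (complete-case rule); the record is later dropped
#' with a logged reason.
#'
#' @param records data.frame with columns `symptom_01..symptom_11` coded
#'   0/1 (or NA).
#' @return integer vector in `[0, 11]`, NA where any item is missing.
#' @export
build_outcome <- function(records) {
  missing_cols <- setdiff(.symptom_cols, names(records))
  if (length(missing_cols))
    stop("build_outcome: missing symptom columns: ",
         paste(missing_cols, collapse = ", "))
  S <- as.matrix(records[, .symptom_cols])
  if (any(S %in% c(0, 1) == FALSE & !is.na(S)))
    stop("build_outcome: symptom items must be 0/1 or NA")
  out <- rowSums(S)
  as.integer(out)
}

#' Encode survey predictors to the regression design coding
#'
#' Maps raw records to the named indicator/continuous coding of the
#' coefficient table: female (vs male); age in raw years; married or in a
#' partnership; lives alone; two education indicators vs up-to-primary;
#' good / very good financial situation vs the four lower answer
#' categories; uses air conditioning (almost) always; self-rated health
#' 0-10; indicators for cardiovascular problems, hypertension, diabetes,
#' respiratory problems, depression; obesity = BMI at or above the cutoff
#' (WHO convention 30); smokes regularly; physically active weekly or more.
#' Unknown category labels are an error listing the offending values.
#'
#' @param records raw survey data.frame (see [simulate_survey()] for the
#'   schema).
#' @param bmi_obesity_cutoff kg/m^2, default 30.
#' @return data.frame of encoded predictor columns in coefficient-table
#'   order; rows with any missing field have NA in the affected column.
#' @export
encode_predictors <- function(records, bmi_obesity_cutoff = 30) {
  chk <- function(x, valid, what) {
    bad <- setdiff(unique(x[!is.na(x)]), valid)
    if (length(bad))
      stop("encode_predictors: unknown ", what, " labels: ",
           paste(sQuote(bad), collapse = ", "))
    x
  }
  ind <- function(x, yes) as.numeric(x == yes)
  sex <- chk(records$sex, c("female", "male"), "sex")
  edu <- chk(records$education, .edu_levels, "education")
  fin <- chk(records$financial_situation,
             c(.fin_very_good, .fin_good, .fin_reference), "financial_situation")
  yn <- c("yes", "no")
  data.frame(
    female = ind(sex, "female"),
    age = as.numeric(records$age),
    married = ind(chk(records$marital, c("married_or_partnership", "not"),
                      "marital"), "married_or_partnership"),
    lives_alone = ind(chk(records$household,
                          c("lives_alone", "lives_with_someone"), "household"),
                      "lives_alone"),
    edu_secondary = ind(edu, "secondary"),
    edu_tertiary = ind(edu, "tertiary_or_postsecondary"),
    fin_good = ind(fin, .fin_good),
    fin_very_good = ind(fin, .fin_very_good),
    ac_always = ind(chk(records$ac_use, c("almost_always", "less_often"),
                        "ac_use"), "almost_always"),
    health = as.numeric(records$health),
    cardio = ind(chk(records$cardiovascular, yn, "cardiovascular"), "yes"),
    hypertension = ind(chk(records$hypertension, yn, "hypertension"), "yes"),
    diabetes = ind(chk(records$diabetes, yn, "diabetes"), "yes"),
    respiratory = ind(chk(records$respiratory, yn, "respiratory"), "yes"),
    depression = ind(chk(records$depression, yn, "depression"), "yes"),
    obesity = as.numeric(records$bmi >= bmi_obesity_cutoff),
    smoking = ind(chk(records$smoking, yn, "smoking"), "yes"),
    active = ind(chk(records$physical_activity,
                     c("weekly_or_more", "less_than_weekly"),
                     "physical_activity"), "weekly_or_more")
  )
}

#' Fit the heat-experience regression
#'
#' Complete-case weighted robust OLS of the 0-11 heat-experience count on
#' the encoded predictors, with HC1 sandwich standard errors and VIF
#' collinearity diagnostics on the final design. Records with a missing
#' outcome item or a missing predictor are dropped and accounted for
#' (`n_input = n_used + n_dropped`, with per-reason counts).
#'
#' @param records raw survey data.frame including symptom items, predictors
#'   and (if `weighted`) a `weight` column.
#' @param weighted use the post-stratification weights (default `TRUE`);
#'   when `FALSE` all weights are 1.
#' @param bmi_obesity_cutoff passed to [encode_predictors()].
#' @return list of class `survey_fit`: `fit` (ols_fit), `tidy`
#'   (coefficient table in the standard row order), `vif`, `drops`
#'   (data.frame reason/n), `n_input`, `n_used`.
#' @export
run_survey_model <- function(records, weighted = TRUE,
                             bmi_obesity_cutoff = 30) {
  n_input <- nrow(records)
  y <- build_outcome(records)
  Z <- encode_predictors(records, bmi_obesity_cutoff)
  zero_var <- names(Z)[vapply(Z, function(v)
    stats::var(v[!is.na(v)]) == 0, logical(1))]
  if (length(zero_var))
    stop("run_survey_model: zero-variance predictors: ",
         paste(zero_var, collapse = ", "))
  w <- if (weighted) {
    if (is.null(records$weight)) stop("weighted fit requires a weight column")
    as.numeric(records$weight)
  } else rep(1, n_input)
  miss_y <- is.na(y)
  miss_x <- !miss_y & rowSums(is.na(Z)) > 0
  miss_w <- !miss_y & !miss_x & (is.na(w) | w <= 0)
  use <- !(miss_y | miss_x | miss_w)
  drops <- data.frame(
    reason = c("missing outcome item", "missing predictor",
               "missing or non-positive weight"),
    n = c(sum(miss_y), sum(miss_x), sum(miss_w)))
  drops <- drops[drops$n > 0, , drop = FALSE]
  n_used <- sum(use)
  if (n_used < 2L * (ncol(Z) + 1L))
    stop("run_survey_model: too few complete records (", n_used,
         ") for ", ncol(Z) + 1L, " parameters")
  X <- cbind(`(Intercept)` = 1, as.matrix(Z[use, , drop = FALSE]))
  fit <- fit_wls_robust(y[use], X, w[use])
  structure(list(fit = fit, tidy = tidy_ols(fit), vif = vif(X),
                 drops = drops, n_input = n_input, n_used = n_used,
                 weighted = weighted),
            class = "survey_fit")
}

#' @export
print.survey_fit <- function(x, ...) {
  cat(sprintf("Heat-experience OLS (%s): n = %d of %d, R2 = %.3f\n",
              if (x$weighted) "weighted, HC1" else "unweighted, HC1",
              x$n_used, x$n_input, x$fit$r_squared))
  print(x$tidy, digits = 3)
  invisible(x)
}
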