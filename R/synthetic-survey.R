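# Shared category labels for the survey schema. The six financial-situation
# answer categories follow the questionnaire wording; the top two map to the
# "very good" / "good" indicators and the remaining four form the reference.
.fin_very_good <- "There is enough for everything without saving in any particular way"
.fin_good <- "I live (we live) frugally and there is enough for everything."
.fin_reference <- c(
  "I live (we live) very frugally to save for bigger purchases.",
  "There is enough money only for the cheapest food and clothes",
  "There is enough money only for the cheapest food, not enough for clothes.",
  "There is not enough money even for the cheapest food or clothes."
)
.edu_levels <- c("up_to_primary", "secondary", "tertiary_or_postsecondary")
.symptom_cols <- sprintf("symptom_%02d", 1:11)

#' Generating coefficients for the Warsaw survey column
#'
#' The named coefficient vector (heat-related experiences per unit of each
#' predictor) used as the generating truth in recovery experiments, on the
#' encoded-predictor scale of [encode_predictors()].
#' @return named numeric vector of 18 coefficients.
#' @export
warsaw_survey_beta <- function() {
  c(female = 0.677, age = -0.0031, married = 0.0782, lives_alone = -0.457,
    edu_secondary = -3.120, edu_tertiary = -2.823,
    fin_good = -0.732, fin_very_good = -0.715,
    ac_always = 0.891, health = -0.296,
    cardio = 0.564, hypertension = 0.113, diabetes = 0.298,
    respiratory = 1.114, depression = 1.801,
    obesity = 0.239, smoking = -0.166, active = 0.523)
}

#' Default covariate model for the survey generator
#'
#' One named entry per generating coefficient. Indicator predictors are
#' Bernoulli; age is uniform over 65-95 integer years; self-rated health is
#' Binomial(10, p) on the 0-10 scale; education and financial situation are
#' categorical with the leftover mass on the reference category.
#'
#' Prevalences are chosen so the latent outcome stays well inside the 0-11
#' observation window under the default generating coefficients (keeping
#' the OLS estimand equal to the generating vector), which takes precedence
#' over demographic realism for the large negative coefficients (education,
#' self-rated health).
#' @return named list of covariate rules.
#' @export
default_covariate_model <- function() {
  list(
    female = list(type = "bernoulli", p = 0.65),
    age = list(type = "uniform_int", min = 65L, max = 95L),
    married = list(type = "bernoulli", p = 0.60),
    lives_alone = list(type = "bernoulli", p = 0.15),
    edu_secondary = list(type = "categorical", group = "education", p = 0.02),
    edu_tertiary = list(type = "categorical", group = "education", p = 0.02),
    fin_good = list(type = "categorical", group = "financial", p = 0.14),
    fin_very_good = list(type = "categorical", group = "financial", p = 0.06),
    ac_always = list(type = "bernoulli", p = 0.55),
    health = list(type = "binomial_int", size = 10L, p = 0.12),
    cardio = list(type = "bernoulli", p = 0.60),
    hypertension = list(type = "bernoulli", p = 0.65),
    diabetes = list(type = "bernoulli", p = 0.30),
    respiratory = list(type = "bernoulli", p = 0.35),
    depression = list(type = "bernoulli", p = 0.35),
    obesity = list(type = "bernoulli", p = 0.35),
    smoking = list(type = "bernoulli", p = 0.10),
    active = list(type = "bernoulli", p = 0.70)
  )
}

#' Survey generator configuration
#'
#' @param n number of respondents (default 1050, the Warsaw sample size).
#' @param beta named generating coefficient vector on the encoded scale.
#' @param intercept latent intercept, experiences (default 3).
#' @param residual_sd latent residual SD, experiences (default 2).
#' @param covariate_model named list of covariate rules; every name in
#'   `beta` must have a matching entry.
#' @param seed integer seed.
#' @return An object of class `survey_sim_config`.
#' @export
survey_sim_config <- function(n = 1050L, beta = warsaw_survey_beta(),
                              intercept = 3, residual_sd = 2,
                              covariate_model = default_covariate_model(),
                              seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (residual_sd < 0) stop("residual_sd must be >= 0")
  missing_rules <- setdiff(names(beta), names(covariate_model))
  if (length(missing_rules))
    stop("no covariate rule for beta entries: ",
         paste(missing_rules, collapse = ", "))
  structure(list(n = n, beta = beta, intercept = intercept,
                 residual_sd = residual_sd,
                 covariate_model = covariate_model, seed = as.integer(seed)),
            class = "survey_sim_config")
}

# draw the encoded covariate matrix for one replicate
.draw_covariates <- function(cm, n) {
  out <- matrix(0, n, length(cm), dimnames = list(NULL, names(cm)))
  done <- character(0)
  for (nm in names(cm)) {
    rule <- cm[[nm]]
    if (identical(rule$type, "categorical")) {
      grp <- rule$group
      if (grp %in% done) next
      members <- names(cm)[vapply(cm, function(r)
        identical(r$type, "categorical") && identical(r$group, grp), logical(1))]
      ps <- vapply(members, function(m) cm[[m]]$p, numeric(1))
      if (sum(ps) >= 1) stop("categorical group '", grp, "' has total p >= 1")
      draw <- sample(c("__ref__", members), n, replace = TRUE,
                     prob = c(1 - sum(ps), ps))
      for (m in members) out[, m] <- as.numeric(draw == m)
      done <- c(done, grp)
    } else if (identical(rule$type, "bernoulli")) {
      out[, nm] <- stats::rbinom(n, 1L, rule$p)
    } else if (identical(rule$type, "uniform_int")) {
      out[, nm] <- sample(rule$min:rule$max, n, replace = TRUE)
    } else if (identical(rule$type, "binomial_int")) {
      out[, nm] <- stats::rbinom(n, rule$size, rule$p)
    } else stop("unknown covariate rule type: ", rule$type)
  }
  out
}

# map encoded covariates back to the raw record schema written to CSV
.encoded_to_raw <- function(X) {
  n <- nrow(X)
  edu <- rep(.edu_levels[1], n)
  edu[X[, "edu_secondary"] == 1] <- .edu_levels[2]
  edu[X[, "edu_tertiary"] == 1] <- .edu_levels[3]
  fin <- sample(.fin_reference, n, replace = TRUE)
  fin[X[, "fin_good"] == 1] <- .fin_good
  fin[X[, "fin_very_good"] == 1] <- .fin_very_good
  obese <- X[, "obesity"] == 1
  bmi <- numeric(n)
  bmi[obese] <- 30 + round(stats::rgamma(sum(obese), shape = 2, scale = 1.8), 1)
  bmi[!obese] <- round(stats::runif(sum(!obese), 19, 29.4), 1)
  yn <- function(v) ifelse(v == 1, "yes", "no")
  data.frame(
    sex = ifelse(X[, "female"] == 1, "female", "male"),
    age = as.integer(X[, "age"]),
    marital = ifelse(X[, "married"] == 1, "married_or_partnership", "not"),
    household = ifelse(X[, "lives_alone"] == 1, "lives_alone",
                       "lives_with_someone"),
    education = edu,
    financial_situation = fin,
    ac_use = ifelse(X[, "ac_always"] == 1, "almost_always", "less_often"),
    health = as.integer(X[, "health"]),
    cardiovascular = yn(X[, "cardio"]),
    hypertension = yn(X[, "hypertension"]),
    diabetes = yn(X[, "diabetes"]),
    respiratory = yn(X[, "respiratory"]),
    depression = yn(X[, "depression"]),
    bmi = bmi,
    smoking = yn(X[, "smoking"]),
    physical_activity = ifelse(X[, "active"] == 1, "weekly_or_more",
                               "less_than_weekly"),
    stringsAsFactors = FALSE
  )
}

#' Simulate survey microdata with known regression coefficients
#'
#' Covariates are drawn per the covariate model; the latent outcome
#' `y* = intercept + x'beta + N(0, residual_sd)` is rounded to the nearest
#' integer and clipped to `[0, 11]`, then decomposed into 11 binary symptom
#' items (a random subset of size y set to "yes") so the table round-trips
#' through [build_outcome()]. Post-stratification weights are drawn
#' log-normal (sdlog 0.2) and normalised to mean 1.
#'
#' @param config a [survey_sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return data.frame with the raw record columns of
#'   [encode_predictors()], `symptom_01..symptom_11`, and `weight`.
#' @export
simulate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "survey_sim_config"))
  set.seed(seed)
  n <- config$n
  X <- .draw_covariates(config$covariate_model, n)
  latent <- config$intercept + drop(X[, names(config$beta)] %*% config$beta) +
    stats::rnorm(n, 0, config$residual_sd)
  y <- pmin(pmax(round(latent), 0L), 11L)
  sym <- matrix(0L, n, 11L, dimnames = list(NULL, .symptom_cols))
  for (i in seq_len(n))
    if (y[i] > 0) sym[i, sample.int(11L, y[i])] <- 1L
  w <- stats::rlnorm(n, 0, 0.2)
  w <- w / mean(w)
  out <- cbind(.encoded_to_raw(X), as.data.frame(sym))
  out$weight <- w
  attr(out, "latent") <- latent
  out
}
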