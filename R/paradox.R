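#' Pair an epidemiological risk contrast with a survey experience term
#'
#' One factor's two sides of the evidence: the mortality relative risk (with
#' 95 percent CI) for the exposed group at a stated temperature percentile,
#' and the corresponding survey coefficient (heat-related experiences) with
#' robust SE and p-value.
#'
#' @param factor factor name (e.g. `"lives_alone"`).
#' @param rr,ci_low,ci_high epidemiological RR and CI, all `> 0`.
#' @param coef,se,p survey coefficient, robust SE, p-value in `[0, 1]`.
#' @param epi_source,survey_source provenance labels.
#' @return An object of class `factor_pair`.
#' @export
factor_pair <- function(factor, rr, ci_low, ci_high, coef, se, p,
                        epi_source = "", survey_source = "") {
  if (!all(is.na(c(rr, ci_low, ci_high))) &&
      any(c(rr, ci_low, ci_high) <= 0, na.rm = TRUE))
    stop("RR and CI must be > 0")
  if (!is.na(p) && (p < 0 || p > 1)) stop("p must be in [0, 1]")
  structure(list(factor = factor, rr = rr, ci_low = ci_low, ci_high = ci_high,
                 coef = coef, se = se, p = p,
                 epi_source = epi_source, survey_source = survey_source),
            class = "factor_pair")
}

#' Assess a factor for the vulnerability paradox
#'
#' A group exhibits the vulnerability paradox when its objective
#' heat-mortality risk is elevated while its self-reported heat experiences
#' are not: people who are more at risk but do not experience or perceive
#' the impacts that could alert them.
#'
#' Decision rule (a declared formalisation - the concept is narrative in the
#' field, so the thresholds are explicit and configurable):
#' \itemize{
#'   \item risk elevated = "yes" if RR > 1 with CI lower bound > 1;
#'     "no" if the CI upper bound < 1; otherwise "indeterminate".
#'   \item experiences elevated = "yes" if coef > 0 with p below
#'     `alpha_survey`; "no" if coef <= 0 with p below `alpha_survey`, or if
#'     |coef| is below the declared negligibility bound; otherwise
#'     "indeterminate".
#'   \item verdict = "paradox" iff risk is "yes" AND experiences are "no";
#'     "aligned" when the two sides agree (yes/yes or no/no); otherwise
#'     "indeterminate" - including the reverse mismatch (risk "no",
#'     experiences "yes"), which is discordant but is not the vulnerability
#'     paradox.
#' }
#' A missing side always yields "indeterminate" with a reason - never a
#' silent paradox.
#'
#' @param pair a [factor_pair()].
#' @param alpha_epi nominal level of the risk CI (0.05: the 95 percent CI
#'   is taken as given in the pair).
#' @param alpha_survey significance level for the survey term (default 0.1,
#'   the coefficient table's outermost star).
#' @param negligible absolute coefficient size treated as no effect
#'   (default 0.1 experiences).
#' @return An object of class `paradox_assessment`: `factor`,
#'   `risk_elevated`, `experiences_elevated`, `verdict`, `reason`.
#' @export
assess_paradox <- function(pair, alpha_epi = 0.05, alpha_survey = 0.1,
                           negligible = 0.1) {
  stopifnot(inherits(pair, "factor_pair"))
  reason <- ""
  if (any(is.na(c(pair$rr, pair$ci_low, pair$ci_high)))) {
    risk <- "indeterminate"; reason <- "epidemiological side missing"
  } else if (pair$rr > 1 && pair$ci_low > 1) {
    risk <- "yes"
  } else if (pair$ci_high < 1) {
    risk <- "no"
  } else risk <- "indeterminate"
  if (any(is.na(c(pair$coef, pair$p)))) {
    exper <- "indeterminate"
    reason <- paste(reason, "survey side missing")
  } else if (pair$p < alpha_survey) {
    exper <- if (pair$coef > 0) "yes" else "no"
  } else if (abs(pair$coef) < negligible) {
    exper <- "no"  # declared negligible
  } else exper <- "indeterminate"
  verdict <- if (risk == "yes" && exper == "no") "paradox"
    else if (risk == "yes" && exper == "yes") "aligned"
    else if (risk == "no" && exper == "no") "aligned"
    else "indeterminate"
  structure(list(factor = pair$factor, risk_elevated = risk,
                 experiences_elevated = exper, verdict = verdict,
                 reason = trimws(reason)),
            class = "paradox_assessment")
}

#' Paradox report over a factor mapping
#'
#' Joins the pipeline's RR table and survey coefficient table through a
#' mapping of factor names and assesses each factor.
#'
#' @param rr data.frame with `stratum`, `percentile`, `rr`, `ci_low`,
#'   `ci_high` (as written by the epi pipeline).
#' @param survey data.frame with `term`, `estimate`, `robust_se`, `p`
#'   (as written by the survey pipeline).
#' @param mapping data.frame with `factor`, `epi_stratum`,
#'   `epi_percentile`, `survey_term`.
#' @param ... passed to [assess_paradox()].
#' @return data.frame: one row per factor with both sides and the verdict.
#' @export
paradox_report <- function(rr, survey, mapping, ...) {
  need <- c("factor", "epi_stratum", "epi_percentile", "survey_term")
  if (!all(need %in% names(mapping)))
    stop("mapping must have columns ", paste(need, collapse = ", "))
  out <- vector("list", nrow(mapping))
  for (i in seq_len(nrow(mapping))) {
    m <- mapping[i, ]
    e <- rr[rr$stratum == m$epi_stratum & rr$percentile == m$epi_percentile, ]
    s <- survey[survey$term == m$survey_term, ]
    if (nrow(e) != 1L)
      stop("paradox_report: no unique RR row for factor ", m$factor,
           " (stratum ", m$epi_stratum, ", percentile ", m$epi_percentile, ")")
    if (nrow(s) != 1L)
      stop("paradox_report: no unique survey term for factor ", m$factor,
           " (term ", m$survey_term, ")")
    pair <- factor_pair(m$factor, e$rr, e$ci_low, e$ci_high,
                        s$estimate, s$robust_se, s$p,
                        epi_source = m$epi_stratum,
                        survey_source = m$survey_term)
    a <- assess_paradox(pair, ...)
    out[[i]] <- data.frame(factor = a$factor, rr = e$rr, ci_low = e$ci_low,
                           ci_high = e$ci_high, coef = s$estimate,
                           p = s$p, risk_elevated = a$risk_elevated,
                           experiences_elevated = a$experiences_elevated,
                           verdict = a$verdict, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
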