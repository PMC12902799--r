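#' Standardize a numeric vector to z-scores
#'
#' @param x Numeric vector (at least two distinct non-missing values);
#'   missing values are preserved.
#' @return `(x - mean) / sd`, with the sample SD (denominator n - 1).
#' @export
zscore <- function(x) {
  v <- x[!is.na(x)]
  if (length(unique(v)) < 2) {
    abort("Cannot z-score a constant (or all-missing) vector.")
  }
  (x - mean(v)) / sd(v)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Omnibus F test for a difference in an index across the three cognitive
#' groups, followed by Tukey's Honestly Significant Difference test with
#' adjusted p-values from the studentized-range distribution.
#'
#' @param data Data frame.
#' @param value Name (string) of the numeric column.
#' @param group Name (string) of the grouping column (>= 3 levels with at
#'   least 2 observations each).
#' @return Object of class `anova_tukey` with elements `statistic` (F),
#'   `p.value`, `df`, and `pairwise` (tibble: `contrast`, `estimate`,
#'   `conf.low`, `conf.high`, `adj.p.value`).
#' @export
anova_tukey <- function(data, value, group) {
  g <- data[[group]]
  if (!is.factor(g)) {
    # fixed byte-order levels so contrast names do not depend on the locale
    g <- factor(g, levels = sort(unique(as.character(g)), method = "radix"))
  }
  df <- tibble::tibble(value = data[[value]], group = g)
  df <- df[stats::complete.cases(df), ]
  df$group <- droplevels(df$group)
  counts <- table(df$group)
  if (length(counts) < 3) abort("At least 3 groups are required.")
  if (any(counts < 2)) abort("Every group needs at least 2 observations.")
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  structure(
    list(
      statistic = an[["F value"]][1],
      p.value = an[["Pr(>F)"]][1],
      df = c(an[["Df"]][1], an[["Df"]][2]),
      group_means = tapply(df$value, df$group, mean),
      pairwise = tibble::tibble(
        contrast = rownames(tk),
        estimate = unname(tk[, "diff"]),
        conf.low = unname(tk[, "lwr"]),
        conf.high = unname(tk[, "upr"]),
        adj.p.value = unname(tk[, "p adj"])
      )
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$statistic, x$p.value))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.anova_tukey <- function(x, ...) x$pairwise

#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 df = x$df[1], df.residual = x$df[2])
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha_family Family-wise error rate in (0, 1).
#' @param n_tests Number of independent tests (the four primary
#'   hemodynamic measures give 0.05 / 4 = 0.0125).
#' @return Per-test significance threshold.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_tests = 4) {
  if (alpha_family <= 0 || alpha_family >= 1) {
    abort("`alpha_family` must be in (0, 1).")
  }
  if (n_tests < 1) abort("`n_tests` must be at least 1.")
  alpha_family / n_tests
}

# Internals shared by the regression battery -------------------------------

# z-score numeric covariates within the analyzed subsample; leave factors
# and logicals to model.matrix contrasts.
std_model_frame <- function(data, vars) {
  out <- data[, vars, drop = FALSE]
  for (nm in names(out)) {
    v <- out[[nm]]
    if (is.character(v)) v <- out[[nm]] <- factor(v)
    if (is.numeric(v)) {
      if (length(unique(v)) < 2) {
        abort(sprintf("Variable `%s` is constant in the analyzed sample.", nm))
      }
      out[[nm]] <- zscore(v)
    } else if ((is.factor(v) && nlevels(droplevels(v)) < 2) ||
               (is.logical(v) && length(unique(v)) < 2)) {
      abort(sprintf("Variable `%s` is constant in the analyzed sample.", nm))
    } else if (is.factor(v)) {
      out[[nm]] <- droplevels(v)
    }
  }
  out
}

std_lm <- function(data, formula_terms, response, min_n = 20) {
  vars <- unique(c(
    all.vars(str2lang(response)),
    unlist(lapply(formula_terms, function(t) all.vars(str2lang(t))))
  ))
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  if (nrow(d) < min_n) {
    abort(sprintf("Only %d complete cases (minimum %d).", nrow(d), min_n),
          class = "hemodyn_insufficient_n")
  }
  d <- std_model_frame(d, vars)
  fml <- stats::reformulate(formula_terms, response = response)
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Perfect collinearity among predictors: ", toString(bad)),
          class = "hemodyn_estimation_failure")
  }
  list(fit = fit, n = nrow(d))
}

term_result <- function(fit, n, term_pattern, predictor, outcome, covariates) {
  cf <- summary(fit)$coefficients
  hit <- grep(term_pattern, rownames(cf))
  if (length(hit) != 1) {
    abort(sprintf("Term matching '%s' not found uniquely.", term_pattern))
  }
  est <- cf[hit, "Estimate"]
  se <- cf[hit, "Std. Error"]
  dof <- fit$df.residual
  ci <- est + c(-1, 1) * qt(0.975, dof) * se
  tibble::tibble(
    predictor = predictor, outcome = outcome,
    beta = est, conf.low = ci[1], conf.high = ci[2],
    p.value = 2 * pt(-abs(est / se), dof), n = n,
    covariates = paste(covariates, collapse = "+")
  )
}

#' Covariate-adjusted standardized association
#'
#' OLS regression of the z-scored outcome on the z-scored hemodynamic
#' index plus the standard covariate set (age, sex, site, APOE
#' epsilon-4 status and total MoCA score, with intracranial volume added
#' automatically for the volumetric outcomes). Continuous variables are
#' standardized within the analyzed (complete-case) subsample, so the
#' reported coefficient is a standardized beta.
#'
#' @param data Cohort tibble (one row per subject).
#' @param index,outcome Column names (strings).
#' @param covariates Character vector of covariate columns.
#' @param icv_outcomes Outcomes that additionally adjust for `icv`.
#' @param min_n Minimum complete cases.
#' @return One-row tibble: `predictor`, `outcome`, `beta`, `conf.low`,
#'   `conf.high`, `p.value`, `n`, `covariates`.
#' @export
fit_association <- function(data, index, outcome,
                            covariates = c("age", "sex", "site", "apoe_e4", "moca"),
                            icv_outcomes = c("wmh_volume", "hippocampal_volume"),
                            min_n = 20) {
  covs <- covariates
  if (outcome %in% icv_outcomes && "icv" %in% names(data) &&
      !"icv" %in% covs) {
    covs <- c(covs, "icv")
  }
  terms <- c(sprintf("`%s`", index), sprintf("`%s`", covs))
  m <- std_lm(data, terms, sprintf("`%s`", outcome), min_n = min_n)
  term_result(m$fit, m$n, paste0("^`?", index, "`?$"), index, outcome, covs)
}

#' Associations within cognitive strata
#'
#' Refits [fit_association()] separately in the cognitively unimpaired
#' (CN) and impaired (MCI + dementia) strata defined from the `diagnosis`
#' column.
#'
#' @inheritParams fit_association
#' @param diagnosis Column with levels CN/MCI/dementia.
#' @return Tibble with one row per stratum; strata below `min_n` complete
#'   cases are flagged `available = FALSE` with missing estimates.
#' @export
stratified_association <- function(data, index, outcome,
                                   covariates = c("age", "sex", "site", "apoe_e4", "moca"),
                                   diagnosis = "diagnosis", min_n = 20) {
  strata <- list(
    unimpaired = data[[diagnosis]] == "CN",
    impaired = data[[diagnosis]] %in% c("MCI", "dementia")
  )
  purrr::map_dfr(names(strata), function(s) {
    d <- data[strata[[s]] & !is.na(data[[diagnosis]]), , drop = FALSE]
    res <- tryCatch(
      fit_association(d, index, outcome, covariates, min_n = min_n),
      error = function(e) NULL
    )
    if (is.null(res)) {
      tibble::tibble(predictor = index, outcome = outcome, beta = NA_real_,
                     conf.low = NA_real_, conf.high = NA_real_,
                     p.value = NA_real_, n = nrow(d),
                     covariates = paste(covariates, collapse = "+"),
                     stratum = s, available = FALSE)
    } else {
      dplyr::mutate(res, stratum = s, available = TRUE)
    }
  })
}

#' Index-by-MoCA interaction on a neuroimaging outcome
#'
#' Adds the product of the z-scored index and z-scored MoCA score to the
#' covariate-adjusted model and reports the interaction coefficient,
#' testing whether cognitive performance moderates the association.
#'
#' @inheritParams fit_association
#' @param moca MoCA column name.
#' @return One-row tibble for the product term.
#' @export
moca_interaction <- function(data, index, outcome,
                             covariates = c("age", "sex", "site", "apoe_e4", "moca"),
                             icv_outcomes = c("wmh_volume", "hippocampal_volume"),
                             moca = "moca", min_n = 20) {
  covs <- unique(c(covariates, moca))
  if (outcome %in% icv_outcomes && "icv" %in% names(data)) covs <- c(covs, "icv")
  terms <- c(sprintf("`%s` * `%s`", index, moca), sprintf("`%s`", setdiff(covs, moca)))
  m <- std_lm(data, terms, sprintf("`%s`", outcome), min_n = min_n)
  term_result(m$fit, m$n, ":", paste0(index, ":", moca), outcome, covs)
}

#' Association between a hemodynamic index and cognition
#'
#' Regression of the z-scored total MoCA score on the z-scored index,
#' adjusting for age and sex.
#'
#' @inheritParams fit_association
#' @param moca MoCA column name.
#' @return One-row tibble for the index coefficient.
#' @export
index_cognition_association <- function(data, index, moca = "moca",
                                        covariates = c("age", "sex"),
                                        min_n = 20) {
  terms <- c(sprintf("`%s`", index), sprintf("`%s`", covariates))
  m <- std_lm(data, terms, sprintf("`%s`", moca), min_n = min_n)
  term_result(m$fit, m$n, paste0("^`?", index, "`?$"), index, moca, covariates)
}

#' Generic nuisance-covariate screen
#'
#' Regresses an index on a candidate nuisance covariate (e.g. the
#' transcranial-Doppler recording hemisphere) plus age and sex, and
#' reports the covariate's coefficient — used to decide whether the
#' nuisance variable needs to enter the main models.
#'
#' @param data Cohort tibble.
#' @param values Index column name (the regression outcome here).
#' @param covariate Candidate nuisance column name.
#' @param adjust Additional adjustment columns.
#' @param min_n Minimum complete cases.
#' @return One-row tibble for the covariate's coefficient.
#' @export
covariate_check <- function(data, values, covariate,
                            adjust = c("age", "sex"), min_n = 20) {
  terms <- c(sprintf("`%s`", covariate), sprintf("`%s`", adjust))
  m <- std_lm(data, terms, sprintf("`%s`", values), min_n = min_n)
  term_result(m$fit, m$n, paste0("^`?", covariate), covariate, values, adjust)
}

#' Full index-by-outcome association battery
#'
#' Runs [fit_association()] for every index x outcome pair and annotates
#' each cell against the Bonferroni-corrected threshold
#' (`significant` below it, `trend` between it and 0.05, `ns` otherwise),
#' mirroring the reporting convention of covariate-adjusted cohort
#' analyses.
#'
#' @param data Cohort tibble containing index and outcome columns.
#' @param indices Character vector of index columns.
#' @param outcomes Character vector of outcome columns.
#' @param alpha_family Family-wise alpha.
#' @param n_tests Number of independent primary measures for the
#'   Bonferroni correction (default: the four pathway indices).
#' @inheritParams fit_association
#' @return Tibble with one row per pair, of class `assoc_table`.
#' @export
association_table <- function(data,
                              indices = c("DVR", "DCA", "COCR", "COPR", "composite_COR"),
                              outcomes = c("wmh_volume", "meta_roi_thickness",
                                           "hippocampal_volume", "amyloid_suvr"),
                              covariates = c("age", "sex", "site", "apoe_e4", "moca"),
                              alpha_family = 0.05, n_tests = 4, min_n = 20) {
  thr <- bonferroni_threshold(alpha_family, n_tests)
  grid <- tidyr::expand_grid(index = indices, outcome = outcomes)
  out <- purrr::pmap_dfr(grid, function(index, outcome) {
    res <- tryCatch(
      fit_association(data, index, outcome, covariates, min_n = min_n),
      error = function(e) tibble::tibble(
        predictor = index, outcome = outcome, beta = NA_real_,
        conf.low = NA_real_, conf.high = NA_real_, p.value = NA_real_,
        n = NA_integer_, covariates = paste(covariates, collapse = "+")
      )
    )
    res
  })
  out$label <- dplyr::case_when(
    is.na(out$p.value) ~ "unavailable",
    out$p.value < thr ~ "significant",
    out$p.value < 0.05 ~ "trend",
    TRUE ~ "ns"
  )
  attr(out, "bonferroni") <- thr
  class(out) <- c("assoc_table", class(out))
  out
}
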