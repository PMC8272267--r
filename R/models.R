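# The two inferential models: a Gaussian LMM for stopover counts per
# migration and a binomial GLMM for proportion of activity during
# stopovers, plus greedy correlation-based predictor pruning.

#' Greedy correlation pruning of predictors
#'
#' Walks the predictors in `priority_order`; a predictor is retained iff
#' its absolute Pearson correlation with every already-retained predictor
#' is at most `threshold`. Constant predictors are dropped with a warning
#' (their correlation is undefined). The result depends only on the
#' priority order, not on row order.
#'
#' @param predictor_table data frame of numeric predictors.
#' @param priority_order character vector ranking all columns to consider,
#'   most ecologically relevant first.
#' @param threshold correlation threshold in (0, 1) (default 0.6).
#' @return character vector of retained predictor names.
#' @export
prune_correlated_predictors <- function(predictor_table, priority_order,
                                        threshold = 0.6) {
  stopifnot(threshold > 0, threshold < 1)
  priority_order <- priority_order[priority_order %in% names(predictor_table)]
  retained <- character(0)
  for (p in priority_order) {
    x <- predictor_table[[p]]
    if (!is.numeric(x) || length(unique(x[is.finite(x)])) < 2) {
      warning(sprintf("predictor '%s' is constant or non-numeric; dropped", p))
      next
    }
    ok <- TRUE
    for (q in retained) {
      r <- suppressWarnings(cor(x, predictor_table[[q]],
                                use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > threshold) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, p)
  }
  retained
}

#' Linear mixed model for stopover counts per migration
#'
#' `count ~ population * season + (1 | individual_id)` with Gaussian
#' errors and identity link (counts are modelled on the linear scale, as
#' is conventional for this design; a Poisson GLMM is available via
#' `family = "poisson"` but is not the validated default). Factors use
#' reference-level coding; a factor with a single observed level is
#' dropped from the fixed effects with a warning.
#'
#' @param migration_table data frame with `count`, `population`, `season`,
#'   `individual_id`.
#' @param family `"gaussian"` (default) or `"poisson"`.
#' @return a `count_model_result` list: `terms` (name, beta, se, t),
#'   `random_effect_sd`, `n_obs`, `fit`.
#' @export
fit_stopover_count_model <- function(migration_table,
                                     family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  d <- migration_table
  need <- c("count", "population", "season", "individual_id")
  stopifnot(all(need %in% names(d)))
  d$population <- factor(d$population)
  d$season <- factor(d$season)
  fixed <- c()
  if (nlevels(droplevels(d$population)) >= 2) fixed <- c(fixed, "population")
  else warning("single population level; dropping population term")
  if (nlevels(droplevels(d$season)) >= 2) fixed <- c(fixed, "season")
  else warning("single season level; dropping season term")
  rhs <- if (length(fixed) == 2) "population * season"
  else if (length(fixed) == 1) fixed
  else "1"
  form <- as.formula(paste("count ~", rhs, "+ (1 | individual_id)"))
  fit <- if (family == "gaussian") {
    lme4::lmer(form, data = d, REML = TRUE)
  } else {
    lme4::glmer(form, data = d, family = stats::poisson())
  }
  sm <- summary(fit)$coefficients
  terms <- data.frame(name = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"], t = sm[, 3],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_sd <- setNames(vc$sdcor, paste(vc$grp, vc$var1, sep = "."))
  structure(list(terms = terms, random_effect_sd = re_sd,
                 n_obs = nrow(d), fit = fit),
            class = "count_model_result")
}

#' Binomial GLMM for proportion of activity during stopovers
#'
#' Logit-link binomial GLMM with successes = active daytime hours and
#' trials = daytime hours, fixed effects the per-stopover mean weather
#' covariates (unscaled), and random intercepts for individuals nested
#' within population.
#'
#' @param stopover_table data frame with `n_active_h`, `n_daytime_h`,
#'   `individual_id`, `population` and the predictor columns.
#' @param retained_predictors character vector of predictor column names
#'   (e.g. from [prune_correlated_predictors()]).
#' @return an `activity_model_result` list: `terms` (name, beta, se, z,
#'   p), `random_effect_sd`, `n_obs`, `converged`, `fit`.
#' @export
fit_activity_glmm <- function(stopover_table, retained_predictors) {
  d <- stopover_table
  need <- c("n_active_h", "n_daytime_h", "individual_id", "population")
  stopifnot(all(need %in% names(d)))
  d <- d[is.finite(d$n_daytime_h) & d$n_daytime_h > 0, , drop = FALSE]
  d <- d[complete.cases(d[, retained_predictors, drop = FALSE]), , drop = FALSE]
  if (length(unique(d$individual_id)) < 2) {
    stop("activity GLMM needs at least 2 individuals (random-effect degeneracy)")
  }
  form <- as.formula(paste(
    "cbind(n_active_h, n_daytime_h - n_active_h) ~",
    paste(retained_predictors, collapse = " + "),
    "+ (1 | population/individual_id)"
  ))
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::binomial()),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    !any(grepl("failed to converge", msgs))
  sm <- summary(fit)$coefficients
  terms <- data.frame(name = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"], z = sm[, "z value"],
                      p = sm[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_sd <- setNames(vc$sdcor, paste(vc$grp, vc$var1, sep = "."))
  structure(list(terms = terms, random_effect_sd = re_sd, n_obs = nrow(d),
                 converged = conv, messages = msgs, fit = fit),
            class = "activity_model_result")
}

#' Coefficient table of a fitted model result
#' @param result a `count_model_result` or `activity_model_result`.
#' @return the `terms` data frame.
#' @export
coef_table <- function(result) result$terms
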