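#' Pooled group summary statistics
#'
#' Combines per-species summary rows (n, mean, sd) into a pooled group mean
#' and standard deviation, e.g. pooling flight initiation distances over all
#' plover and courser species. The pooled mean is the sample-size-weighted
#' mean; the pooled variance combines within-species and between-species terms:
#' `[sum((n_i - 1) s_i^2) + sum(n_i (m_i - m)^2)] / (N - 1)`.
#'
#' @param summaries data.frame with columns `n`, `mean`, `sd` (one row per
#'   species; `sd` may be NA for n = 1 groups, whose within term is zero).
#' @return list with pooled `n`, `mean`, `sd`.
#' @export
pooled_group_stats <- function(summaries) {
  if (!nrow(summaries)) stop("no groups to pool")
  if (!all(c("n", "mean", "sd") %in% names(summaries)))
    stop("summaries needs columns n, mean, sd")
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  if (any(n < 1)) stop("each group needs n >= 1")
  s[n == 1] <- 0
  if (any(is.na(s) | s < 0)) stop("group sd must be >= 0")
  N <- sum(n)
  mbar <- sum(n * m) / N
  if (N == 1) return(list(n = N, mean = mbar, sd = s[1]))
  v <- (sum((n - 1) * s^2) + sum(n * (m - mbar)^2)) / (N - 1)
  list(n = N, mean = mbar, sd = sqrt(v))
}

#' Median split of a camouflage metric
#'
#' Labels each nest "low" or "high" according to whether its metric is below
#' or above the sample median; values equal to the median are assigned "low".
#'
#' @param values numeric metric per nest (length >= 2).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  med <- median(values)
  factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
}

check_outcomes <- function(outcomes) {
  if (!all(c("time_days", "event") %in% names(outcomes)))
    stop("outcomes needs columns time_days, event")
  if (any(outcomes$time_days <= 0)) stop("observation times must be > 0")
  if (!all(outcomes$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(outcomes)
}

#' Kaplan-Meier survival curves with 95% confidence intervals
#'
#' Product-limit estimator of clutch survival per group with Greenwood
#' variance and log-transformed 95% confidence intervals (clipped to [0, 1]).
#' Censored nests (deserted, trampled, season end, unknown fate) contribute
#' up to their last known date.
#'
#' @param outcomes data.frame with `time_days` (> 0) and `event` (1 =
#'   depredated, 0 = censored or hatched).
#' @param groups optional factor of group labels (e.g. a [median_split()]).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, `ci_low`, `ci_high`.
#' @export
kaplan_meier <- function(outcomes, groups = NULL) {
  check_outcomes(outcomes)
  if (is.null(groups)) groups <- factor(rep("all", nrow(outcomes)))
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty group")
  d <- data.frame(time = outcomes$time_days, event = outcomes$event,
                  group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d,
                           conf.type = "log", conf.int = 0.95)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(groups)[1], length(s$time))
         else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, survival = s$surv,
             ci_low = pmax(ifelse(is.na(s$lower), 0, s$lower), 0),
             ci_high = pmin(ifelse(is.na(s$upper), 1, s$upper), 1))
}

#' Cox proportional-hazards association between metrics and predation
#'
#' Fits a fixed-effects Cox proportional-hazards model of predation hazard on
#' one or more camouflage metrics (Efron approximation for tied event times).
#' Covariates are standardized internally (zero mean, unit SD) so coefficients
#' are log hazard ratios per covariate SD. Species may be entered as strata,
#' letting each species keep its own baseline hazard while the camouflage
#' effect is shared.
#'
#' @param outcomes data.frame with `time_days` and `event` (1 = depredated).
#' @param covariates numeric vector, matrix or data.frame of per-nest metrics
#'   (rows match `outcomes`).
#' @param strata optional factor (e.g. species) for stratified baselines.
#' @param standardize standardize covariates first (default TRUE).
#' @return data.frame with one row per covariate: `term`, `beta`, `se`, `z`,
#'   `p`.
#' @export
cox_ph <- function(outcomes, covariates, strata = NULL, standardize = TRUE) {
  check_outcomes(outcomes)
  if (sum(outcomes$event) < 1)
    stop("no predation events: Cox model cannot be fitted")
  x <- as.matrix(covariates)
  if (is.null(colnames(x)))
    colnames(x) <- if (ncol(x) == 1) "metric" else paste0("metric", seq_len(ncol(x)))
  if (any(!is.finite(x))) stop("covariates must be finite")
  if (nrow(x) != nrow(outcomes)) stop("covariate rows must match outcomes")
  if (standardize)
    x <- scale(x)
  d <- data.frame(time = outcomes$time_days, event = outcomes$event, x,
                  check.names = FALSE)
  rhs <- paste(sprintf("`%s`", colnames(x)), collapse = " + ")
  if (!is.null(strata)) {
    d$.strata <- as.factor(strata)
    rhs <- paste(rhs, "+ strata(.strata)")
  }
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
    data = d, ties = "efron")
  sm <- summary(fit)
  data.frame(term = colnames(x),
             beta = unname(sm$coefficients[, "coef"]),
             se = unname(sm$coefficients[, "se(coef)"]),
             z = unname(sm$coefficients[, "z"]),
             p = unname(sm$coefficients[, "Pr(>|z|)"]),
             row.names = NULL)
}

#' Fixed-effects logistic interaction between target and background contrast
#'
#' Approximation (clearly labelled as such) to a mixed-model interaction
#' analysis: models the probability that a clutch survived to hatching as a
#' fixed-effects logistic regression on target contrast, background contrast
#' and their interaction. Censored nests must be excluded by the caller, since
#' a binary fate model cannot use partial observation times.
#'
#' @param survived 0/1 vector (1 = hatched).
#' @param target_contrast,background_contrast per-nest metrics.
#' @return list with the `glm` fit and a coefficient table; the interaction
#'   term tests whether survivors show a steeper target-background contrast
#'   correlation.
#' @export
fate_interaction_glm <- function(survived, target_contrast, background_contrast) {
  if (!all(survived %in% c(0, 1))) stop("survived must be 0/1")
  d <- data.frame(survived = survived, t = target_contrast,
                  b = background_contrast)
  fit <- glm(survived ~ t * b, family = binomial(), data = d)
  co <- summary(fit)$coefficients
  list(fit = fit,
       coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                                 se = co[, 2], z = co[, 3], p = co[, 4],
                                 row.names = NULL),
       note = "fixed-effects approximation to a mixed-model interaction analysis")
}

#' Read nest outcome tables
#'
#' @param path CSV with columns `nest_id`, `species`, `time_days`, `event`,
#'   `censor_reason`.
#' @return validated data.frame.
#' @export
read_outcomes <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  check_outcomes(d)
  d
}
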