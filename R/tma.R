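#' Categorize immunohistochemical nuclear staining
#'
#' Maps the percentage of positively stained nuclei to the six-group ordinal
#' score: 0 no nuclear staining; 1+ (<10\%); 2+ (10--25\%); 3+ (26--50\%);
#' 4+ (51--75\%); 5+ (>75\%).  Non-integer boundary values are resolved
#' upper-inclusive: (0,10) -> 1, [10,25] -> 2, (25,50] -> 3, (50,75] -> 4,
#' (75,100] -> 5.
#'
#' @param percentPositive numeric vector in [0, 100].
#' @param anyNuclear logical vector: any nuclear staining at all?  FALSE
#'   forces category 0.
#' @return Integer vector of categories 0--5.
#' @examples
#' categorizeStaining(c(5, 30, 80), anyNuclear = c(TRUE, TRUE, TRUE))
#' @export
categorizeStaining <- function(percentPositive, anyNuclear = TRUE) {
  if (any(percentPositive < 0 | percentPositive > 100))
    stop("percentPositive must lie in [0, 100]", call. = FALSE)
  anyNuclear <- rep_len(anyNuclear, length(percentPositive))
  cat <- ifelse(percentPositive < 10, 1L,
         ifelse(percentPositive <= 25, 2L,
         ifelse(percentPositive <= 50, 3L,
         ifelse(percentPositive <= 75, 4L, 5L))))
  as.integer(ifelse(!anyNuclear, 0L, cat))
}

#' Dichotomize a staining category into low/high expression
#'
#' Categories at or below the cutoff (default 2) are "low"; above, "high" —
#' i.e. low staining is <= 2+ and high staining is >= 3+.
#'
#' @param category integer vector of staining categories 0--5.
#' @param cutoff highest category still called low.
#' @return Factor with levels \code{low}, \code{high}.
#' @export
dichotomize <- function(category, cutoff = 2L) {
  if (any(category < 0 | category > 5))
    stop("categories must lie in 0..5", call. = FALSE)
  factor(ifelse(category <= cutoff, "low", "high"),
         levels = c("low", "high"))
}

## round half away from zero, as printed clinical tables do
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Stratified cohort summary table
#'
#' Produces the clinicopathological summary: the staining-category
#' distribution, the AR low/high split among evaluable patients, and for
#' each stratum of each feature the case count with column percentage plus
#' AR-high and AR-low counts with within-row percentages.  Percentages are
#' rounded half-up to one decimal.
#'
#' @param cohort data.frame with at least \code{ar_category}; the feature
#'   columns \code{age_years}, \code{gender}, \code{grade},
#'   \code{metastasis}, \code{recurrence}, \code{chemo_response} are
#'   summarized when present.
#' @param cutoff dichotomization cutoff passed to [dichotomize()].
#' @param ageSplit age threshold separating the two age strata.
#' @return A list with \code{staining} (category, n, percent),
#'   \code{arGroups} (group, n, percent) and \code{features} (feature,
#'   level, n, percent, ar_high_n, ar_high_pct, ar_low_n, ar_low_pct).
#' @examples
#' counts <- c(5, 24, 22, 19, 15, 2)
#' cohort <- data.frame(ar_category = rep(0:5, counts))
#' cohortSummary(cohort)$arGroups
#' @export
cohortSummary <- function(cohort, cutoff = 2L, ageSplit = 24) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  n <- nrow(cohort)
  cat <- cohort$ar_category
  staining <- data.frame(category = 0:5,
                         n = as.vector(table(factor(cat, levels = 0:5))))
  staining$percent <- roundHalfUp(100 * staining$n / n)
  grp <- dichotomize(cat, cutoff)
  arGroups <- data.frame(group = levels(grp),
                         n = as.vector(table(grp)))
  arGroups$percent <- roundHalfUp(100 * arGroups$n / n)

  strata <- list()
  addFeature <- function(feature, values) {
    values <- as.character(values)
    for (lev in sort(unique(na.omit(values)))) {
      inLev <- !is.na(values) & values == lev
      nl <- sum(inLev)
      hi <- sum(grp[inLev] == "high")
      strata[[length(strata) + 1]] <<- data.frame(
        feature = feature, level = lev, n = nl,
        percent = roundHalfUp(100 * nl / n),
        ar_high_n = hi, ar_high_pct = roundHalfUp(100 * hi / nl),
        ar_low_n = nl - hi, ar_low_pct = roundHalfUp(100 * (nl - hi) / nl))
    }
  }
  if (!is.null(cohort$age_years))
    addFeature("age", ifelse(cohort$age_years <= ageSplit,
                             sprintf("<=%d", ageSplit),
                             sprintf(">%d", ageSplit)))
  if (!is.null(cohort$age_group)) addFeature("age", cohort$age_group)
  for (f in c("gender", "grade", "metastasis", "recurrence",
              "chemo_response"))
    if (!is.null(cohort[[f]])) addFeature(f, cohort[[f]])

  features <- if (length(strata)) do.call(rbind, strata) else
    data.frame(feature = character(), level = character(), n = integer(),
               percent = numeric(), ar_high_n = integer(),
               ar_high_pct = numeric(), ar_low_n = integer(),
               ar_low_pct = numeric())
  list(staining = staining, arGroups = arGroups, features = features,
       nPatients = n)
}

#' Pearson chi-square test of independence on a contingency table
#'
#' Pearson statistic \eqn{\sum (O-E)^2/E} with expected counts from the
#' margins, df = (r-1)(c-1), upper-tail chi-square p-value; optional Yates
#' continuity correction for 2x2 tables.  Delegates to
#' \code{stats::chisq.test}.
#'
#' @param table matrix of nonnegative counts with positive row and column
#'   sums.
#' @param yates apply the continuity correction (2x2 only).
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @examples
#' chiSquare(rbind(c(6, 3), c(10, 27)))
#' @export
chiSquare <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin", call. = FALSE)
  res <- suppressWarnings(chisq.test(table, correct = yates))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Spearman rank correlation with mid-rank tie handling
#'
#' The Pearson correlation of mid-ranks, i.e. the tie-corrected Spearman
#' coefficient.
#'
#' @param x,y equal-length vectors (length >= 3) of ordinal or numeric
#'   values.
#' @return rho in [-1, 1].
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance; Spearman correlation undefined", call. = FALSE)
  cor(rank(x), rank(y))
}

#' Kaplan-Meier product-limit survival curve
#'
#' Censoring at an event time follows the standard convention (censored
#' subjects remain at risk for the events at that time and leave the risk
#' set afterwards).  Delegates to \code{survival::survfit}.
#'
#' @param times nonnegative follow-up times.
#' @param events logical/0-1 event indicators.
#' @return data.frame with \code{time}, \code{n_risk}, \code{n_event},
#'   \code{surv} (step-function values, non-increasing from 1).
#' @examples
#' kaplanMeier(c(1, 2, 3), c(1, 0, 1))
#' @export
kaplanMeier <- function(times, events) {
  if (any(times < 0)) stop("negative follow-up time", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Log-rank test for differences between survival curves
#'
#' Standard observed-minus-expected statistic with hypergeometric variance
#' at each event time, df = number of groups - 1.  Delegates to
#' \code{survival::survdiff}.
#'
#' @param groups group labels (>= 2 nonempty groups).
#' @param times,events as in [kaplanMeier()].
#' @return List with \code{statistic}, \code{df} and \code{p}.
#' @export
logRank <- function(groups, times, events) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop("need at least 2 nonempty groups", call. = FALSE)
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ groups)
  df <- nlevels(groups) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Breslow tie handling by default,
#' Efron available) and reports coefficients, standard errors from the
#' observed information, hazard ratios and Wald 95\% confidence intervals.
#' Delegates to \code{survival::coxph}.
#'
#' @param covariates data.frame or matrix of covariates (no constant
#'   columns).
#' @param times,events as in [kaplanMeier()].
#' @param ties "breslow" (default) or "efron".
#' @return List of class \code{coxSummary}: \code{coef}, \code{se},
#'   \code{z}, \code{p}, \code{hr}, \code{ci_lower}, \code{ci_upper},
#'   \code{loglik}, \code{n}, \code{nevent}, \code{fit} (the underlying
#'   \code{coxph} object).
#' @export
coxFit <- function(covariates, times, events, ties = "breslow") {
  x <- as.data.frame(covariates)
  if (any(vapply(x, function(v) length(unique(v[!is.na(v)])) < 2,
                 logical(1))))
    stop("constant covariate", call. = FALSE)
  if (sum(events) < 1) stop("no events", call. = FALSE)
  dat <- cbind(x, .time = times, .event = as.integer(events))
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = dat, ties = ties)
  if (anyNA(coef(fit)) || any(!is.finite(coef(fit))) ||
      any(abs(coef(fit)) > 20))
    stop("Cox fit did not converge (possible monotone likelihood)",
         call. = FALSE)
  s <- summary(fit)
  out <- list(coef = coef(fit), se = s$coefficients[, "se(coef)"],
              z = s$coefficients[, "z"],
              p = s$coefficients[, "Pr(>|z|)"],
              hr = exp(coef(fit)),
              ci_lower = s$conf.int[, "lower .95"],
              ci_upper = s$conf.int[, "upper .95"],
              loglik = fit$loglik[2], n = fit$n, nevent = fit$nevent,
              fit = fit)
  class(out) <- "coxSummary"
  out
}

#' @export
print.coxSummary <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$n, " subjects, ", x$nevent,
      " events)\n", sep = "")
  print(data.frame(coef = x$coef, se = x$se, p = x$p, HR = x$hr,
                   lower95 = x$ci_lower, upper95 = x$ci_upper))
  invisible(x)
}

#' Stepwise Cox model selection
#'
#' Forward selection with backward pruning on Wald p-values: at each
#' forward step the candidate with the smallest Wald p below
#' \code{pEnter} joins the model (ties broken by smaller p, then
#' lexicographic name); after each addition, included covariates with Wald
#' p above \code{pRemove} are pruned (largest p first).  Deterministic
#' given the input.
#'
#' @param covariates data.frame of candidate covariates.
#' @param times,events as in [kaplanMeier()].
#' @param pEnter entry threshold on the Wald p-value.
#' @param pRemove removal threshold.
#' @param ties passed to [coxFit()].
#' @return A list with \code{selected} (covariate names, possibly empty)
#'   and \code{model} (the final [coxFit()] result, or \code{NULL} for an
#'   empty model).
#' @export
stepwiseCox <- function(covariates, times, events, pEnter = 0.05,
                        pRemove = 0.10, ties = "breslow") {
  covariates <- as.data.frame(covariates)
  candidates <- colnames(covariates)
  if (length(candidates) < 1) stop("no candidates", call. = FALSE)
  selected <- character()
  repeat {
    changed <- FALSE
    ## forward step
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      ps <- vapply(pool, function(v) {
        fit <- coxFit(covariates[, c(selected, v), drop = FALSE],
                      times, events, ties)
        unname(fit$p[length(fit$p)])
      }, numeric(1))
      best <- pool[order(ps, pool)][1]
      if (ps[best] < pEnter) {
        selected <- c(selected, best)
        changed <- TRUE
      }
    }
    ## backward pruning
    repeat {
      if (length(selected) == 0) break
      fit <- coxFit(covariates[, selected, drop = FALSE], times, events,
                    ties)
      worstP <- max(fit$p)
      if (worstP <= pRemove) break
      worst <- names(fit$p)[order(-fit$p, names(fit$p))][1]
      selected <- setdiff(selected, worst)
      changed <- TRUE
    }
    if (!changed) break
  }
  model <- if (length(selected))
    coxFit(covariates[, selected, drop = FALSE], times, events, ties)
  else NULL
  list(selected = selected, model = model)
}
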