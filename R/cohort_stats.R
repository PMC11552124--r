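#' Statistical configuration
#'
#' @param screen_p univariate inclusion threshold for the multivariate
#'   logistic stage (default 0.100).
#' @param alpha significance level (default 0.05).
#' @param epsilon IRLS convergence tolerance passed to the logistic fitter
#'   (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 50).
#' @param seed RNG seed for any resampling.
#' @return a \code{stat_config} list.
#' @export
stat_config <- function(screen_p = 0.100, alpha = 0.05, epsilon = 1e-8,
                        max_iter = 50, seed = 1) {
  stopifnot(screen_p > 0, screen_p < 1, alpha > 0, alpha < 1)
  structure(list(screen_p = screen_p, alpha = alpha, epsilon = epsilon,
                 max_iter = max_iter, seed = seed),
            class = "stat_config")
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided rank-sum comparison with midrank tie handling, the group
#' comparison used throughout the cohort analysis. The p value is exact
#' for small untied samples and a tie-corrected normal approximation
#' otherwise (the \code{\link[stats]{wilcox.test}} conventions).
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list: \code{U} (statistic of the first sample), \code{p}
#'   (two-sided).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1)
    return(list(U = length(a) * length(b) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' ROC curve, AUC and confidence interval
#'
#' AUC by the Mann-Whitney identity \code{U / (n1 * n0)} over midranks
#' (equivalently the fraction of concordant case-control pairs, ties
#' counting one half), with a 95\% CI from the Hanley-McNeil standard
#' error, clipped to \code{[0, 1]}. The threshold sweep evaluates
#' sensitivity and specificity at midpoints between adjacent distinct
#' scores (plus the two outer extremes), with positives called at or above
#' the threshold. Higher scores are assumed to indicate the positive
#' class; an AUC below 0.5 simply reports that orientation.
#'
#' @param scores numeric vector.
#' @param labels binary vector (0/1, logical, or two-level factor; the
#'   larger/second level is the positive class). Both classes must be
#'   present.
#' @param conf_level CI level (default 0.95).
#' @return object of class \code{roc_result}: list with \code{auc},
#'   \code{ci} (length 2), \code{se}, and \code{thresholds} data.frame
#'   (\code{cutoff, sensitivity, specificity, youden}).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- as_binary(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)          # midranks
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # Hanley-McNeil SE
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * se))
  u <- sort(unique(scores))
  cuts <- if (length(u) > 1)
    c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  else u
  sens <- vapply(cuts, function(ct) mean(scores[y == 1] >= ct), 0)
  spec <- vapply(cuts, function(ct) mean(scores[y == 0] < ct), 0)
  structure(list(auc = auc, ci = ci, se = se,
                 thresholds = data.frame(cutoff = cuts, sensitivity = sens,
                                         specificity = spec,
                                         youden = sens + spec - 1),
                 n_pos = n1, n_neg = n0,
                 mean_pos = mean(scores[y == 1]),
                 mean_neg = mean(scores[y == 0])),
            class = "roc_result")
}

as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(labels))
  if (length(u) != 2) stop("labels must take exactly two values")
  as.integer(labels == u[2])
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Best operating cutoff by Youden's J
#'
#' Picks the threshold maximising \code{sensitivity + specificity - 1}
#' from a \code{\link{roc_auc}} sweep; thresholds sit at midpoints between
#' adjacent distinct scores. Ties in J are broken toward the cutoff
#' nearest the midpoint of the two class means.
#'
#' @param roc a \code{roc_result}.
#' @return numeric cutoff.
#' @examples
#' r <- roc_auc(c(-2, -1, 1, 2), c(0, 0, 1, 1))
#' best_cutoff(r)   # 0
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  th <- roc$thresholds
  if (nrow(th) < 2) stop("all scores equal: no informative cutoff")
  best <- which(th$youden == max(th$youden))
  if (length(best) > 1) {
    mid <- (roc$mean_pos + roc$mean_neg) / 2
    best <- best[which.min(abs(th$cutoff[best] - mid))]
  }
  th$cutoff[best]
}

#' Fit a multivariate logistic nuclear-morphology score
#'
#' The model-building procedure of the cohort analysis: candidate features
#' are screened by univariate two-group Mann-Whitney comparison at
#' \code{p < screen_p}; the survivors enter a multivariate binomial GLM
#' (iteratively reweighted least squares) whose linear predictor is the
#' nuclear-morphology score. Wald p values are reported per coefficient.
#' Complete separation is flagged (the returned \code{converged} and
#' \code{separation} fields) rather than silently returning runaway
#' coefficients.
#'
#' @param cases data.frame of per-case mean features.
#' @param outcome binary outcome vector (see \code{\link{roc_auc}} label
#'   handling); the second/larger level is modelled as 1.
#' @param candidates character vector of candidate feature columns
#'   (default all six).
#' @param config a \code{\link{stat_config}}.
#' @param cutoff optional decision cutoff for the returned model; default
#'   is the Youden-best cutoff of the fitted scores.
#' @param labels class labels for the returned \code{\link{score_model}}.
#' @return list: \code{model} (a \code{score_model}), \code{fit} (the
#'   \code{glm}), \code{screen} (data.frame of univariate p values and
#'   inclusion flags), \code{p_values} (Wald, per coefficient),
#'   \code{converged}, \code{separation}.
#' @export
fit_logistic_score <- function(cases, outcome,
                               candidates = nuclear_feature_names(),
                               config = stat_config(), cutoff = NULL,
                               labels = c("low", "high")) {
  y <- as_binary(outcome)
  stopifnot(nrow(cases) == length(y), sum(y == 0) >= 2, sum(y == 1) >= 2)
  miss <- setdiff(candidates, names(cases))
  if (length(miss))
    stop("missing candidate feature(s): ", paste(miss, collapse = ", "))
  screen <- data.frame(
    feature = candidates,
    p = vapply(candidates, function(f)
      mann_whitney(cases[[f]][y == 0], cases[[f]][y == 1])$p, 0))
  screen$included <- screen$p < config$screen_p
  sel <- screen$feature[screen$included]
  dat <- cbind(cases[, sel, drop = FALSE], .y = y)
  form <- if (length(sel))
    stats::as.formula(paste(".y ~", paste(sel, collapse = " + ")))
  else stats::as.formula(".y ~ 1")
  fit <- suppressWarnings(stats::glm(
    form, family = stats::binomial(), data = dat,
    control = stats::glm.control(epsilon = config$epsilon,
                                 maxit = config$max_iter)))
  fitted <- stats::fitted(fit)
  separation <- any(fitted > 1 - 1e-8) && any(fitted < 1e-8) &&
    all(abs(fitted - y) < 1e-6)
  if (separation)
    warning("complete separation detected: coefficients are not identified")
  cf <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  p_values <- sm[, "Pr(>|z|)"]
  scores <- as.numeric(stats::predict(fit, type = "link"))
  if (is.null(cutoff)) {
    cutoff <- if (length(unique(scores)) > 1)
      best_cutoff(roc_auc(scores, y)) else 0
  }
  model <- score_model(name = "fitted_logistic", intercept = cf[1],
                       coefficients = cf[-1], cutoff = cutoff,
                       labels = labels)
  list(model = model, fit = fit, screen = screen, p_values = p_values,
       converged = fit$converged && !separation, separation = separation)
}

#' Kaplan-Meier event-free-survival curve
#'
#' Product-limit estimate with Greenwood variance: each event time steps
#' the curve down by the factor \code{1 - d/n}; censored cases leave the
#' risk set without a step. \code{S(0) = 1} and the curve is
#' non-increasing.
#'
#' @param times non-negative follow-up times (months).
#' @param events 0/1 event indicators (1 = recurrence/metastasis).
#' @return data.frame: \code{time, n_risk, n_event, n_censor, surv, se}
#'   (Greenwood), one row per distinct observed time.
#' @export
km_curve <- function(times, events) {
  stopifnot(all(times >= 0), all(events %in% c(0, 1)),
            length(times) == length(events))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "plain")
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv,
             se = sf$std.err * sf$surv)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' chi-square distributed with 1 degree of freedom under the null of equal
#' survival.
#'
#' @param group two-valued group assignment, both groups non-empty.
#' @param times,events as in \code{\link{km_curve}}.
#' @return list: \code{chisq}, \code{p}, \code{df = 1}, \code{obs} and
#'   \code{exp} per group.
#' @export
logrank_test <- function(group, times, events) {
  g <- as_binary(group)
  if (length(unique(g)) != 2) stop("need two non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(chisq = sd$chisq, p = stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
       df = 1, obs = sd$obs, exp = sd$exp)
}

#' Recurrence analysis by a circularity cutoff
#'
#' Dichotomises the cohort at a feature cutoff (default: nuclear
#' circularity at 0.698, the shipped recurrence threshold), then estimates
#' Kaplan-Meier event-free survival and the log-rank comparison for the
#' whole cohort and within each diagnosis/grade stratum with both arms
#' represented.
#'
#' @param cases data.frame with the feature column, \code{time_months},
#'   \code{event}, and (optionally) a \code{group} column of grade labels.
#' @param feature feature column to dichotomise (default
#'   \code{"circularity"}).
#' @param cutoff threshold; values at or above it form the high arm
#'   (default from \code{\link{circularity_recurrence_model}}).
#' @return list: \code{overall} = list(km_low, km_high, logrank, n_low,
#'   n_high), and \code{strata} = named list of the same structure per
#'   grade with both arms present.
#' @export
recurrence_analysis <- function(cases, feature = "circularity",
                                cutoff = NULL) {
  stopifnot(all(c(feature, "time_months", "event") %in% names(cases)))
  if (is.null(cutoff)) cutoff <- circularity_recurrence_model()$cutoff
  arm <- cases[[feature]] >= cutoff
  if (all(arm) || !any(arm))
    stop("cutoff leaves a single arm: nothing to compare")
  one <- function(d, a) list(
    km_low = km_curve(d$time_months[!a], d$event[!a]),
    km_high = km_curve(d$time_months[a], d$event[a]),
    logrank = logrank_test(a, d$time_months, d$event),
    n_low = sum(!a), n_high = sum(a))
  out <- list(cutoff = cutoff, overall = one(cases, arm), strata = list())
  if ("group" %in% names(cases)) {
    for (g in unique(cases$group)) {
      i <- cases$group == g
      if (length(unique(arm[i])) == 2)
        out$strata[[g]] <- one(cases[i, ], arm[i])
    }
  }
  out
}
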