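test_that("Mann-Whitney: exact separated-groups p, symmetry, degenerate ties", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)   # 2/choose(6,3): both extreme arrangements
  # identical samples: U = n^2 / 2
  mw2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(mw2$U, 8)
  expect_equal(mann_whitney(rep(5, 4), rep(5, 3)),
               list(U = 6, p = 1))
})

test_that("Mann-Whitney type-I error is near nominal under the null", {
  set.seed(20)
  rej <- mean(replicate(4000, {
    mann_whitney(rnorm(60), rnorm(60))$p < 0.05
  }))
  expect_equal(rej, 0.05, tolerance = 0.01 / 0.05)   # within +/- 0.01
})

test_that("AUC equals the Mann-Whitney identity and the brute-force pair count", {
  set.seed(21)
  for (i in 1:10) {
    n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
    scores <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))  # with ties
    y <- c(rep(1, n1), rep(0, n0))
    r <- roc_auc(scores, y)
    expect_equal(r$auc, brute_auc(scores, y), tolerance = 1e-12)
    # U / (n1 n0) identity against wilcox.test's statistic
    U <- suppressWarnings(
      stats::wilcox.test(scores[y == 1], scores[y == 0])$statistic)
    expect_equal(r$auc, unname(U) / (n1 * n0), tolerance = 1e-12)
  }
  # perfectly separated scores
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auc, 1)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "two values")
})

test_that("AUC and Hanley-McNeil CI agree with pROC on a worked set", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(80) + rep(c(0, 1), each = 40)
  y <- rep(c(0, 1), each = 40)
  r <- roc_auc(scores, y)
  pr <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  expect_true(r$ci[1] < r$auc && r$auc < r$ci[2])
})

test_that("best cutoff maximises Youden's J and matches exhaustive search", {
  r <- roc_auc(c(-2, -1, 1, 2), c(0, 0, 1, 1))
  expect_equal(best_cutoff(r), 0)
  set.seed(23)
  scores <- c(2.1, 3.3, 3.9, 4.2, 1.8, 3.0, 4.8, 5.5)
  y <- c(0, 0, 0, 1, 0, 1, 1, 1)
  r8 <- roc_auc(scores, y)
  # exhaustive search over all midpoints between adjacent distinct scores
  u <- sort(unique(scores))
  mids <- (u[-1] + u[-length(u)]) / 2
  J <- vapply(mids, function(ct)
    mean(scores[y == 1] >= ct) + mean(scores[y == 0] < ct) - 1, 0)
  expect_equal(best_cutoff(r8), mids[which.max(J)])
  expect_error(best_cutoff(roc_auc(rep(1, 4), c(0, 0, 1, 1))),
               "no informative cutoff")
})

test_that("logistic fitting: balanced intercept-only model and screening rule", {
  set.seed(24)
  coh <- generate_feature_cohort(n_per_group = 60, seed = 24)
  y <- rep(c(0, 1), 120)   # outcome independent of everything, balanced
  fit <- suppressWarnings(
    fit_logistic_score(coh[1:240, ], y, config = stat_config(seed = 1)))
  # features failing the univariate screen stay out of the model
  excluded <- fit$screen$feature[fit$screen$p >= 0.1]
  expect_false(any(excluded %in% names(fit$model$coefficients)))
  # ...and a balanced intercept-only fit has beta0 = log(0.5/0.5) = 0
  fit0 <- fit_logistic_score(coh[1:240, ], y, candidates = character(0))
  expect_equal(unname(fit0$model$intercept), 0, tolerance = 1e-8)
})

test_that("logistic coefficients are recovered within 3 SE on a generated cohort", {
  set.seed(25)
  n <- 5000
  X <- cbind(area_um2 = rnorm(n, 17, 2),
             eccentricity = rnorm(n, 0.8, 0.02))
  beta <- c(intercept = -28.5, area_um2 = 0.5, eccentricity = 25)
  eta <- beta[1] + X %*% beta[-1]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic_score(as.data.frame(X), y,
                            candidates = c("area_um2", "eccentricity"))
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  est <- c(fit$model$intercept, fit$model$coefficients)
  expect_true(all(abs(est - beta) < 3 * se))
  expect_true(fit$converged)
})

test_that("complete separation is flagged, not silently returned", {
  d <- data.frame(area_um2 = c(1:10, 21:30))
  y <- rep(c(0, 1), each = 10)
  expect_warning(
    fit <- fit_logistic_score(d, y, candidates = "area_um2"),
    "separation")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("Kaplan-Meier estimates match hand product-limit computations", {
  # all events at distinct times: S = empirical survival
  k1 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k1$surv, c(2 / 3, 1 / 3, 0))
  # no events: S stays 1
  k2 <- km_curve(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(k2$surv == 1))
  # mixed set {6E,6E,6E,6C,7E,9C,10E}, hand product-limit:
  #  t=6: 7 at risk, 3 events -> 4/7
  #  t=7: 3 at risk, 1 event  -> 4/7 * 2/3 = 8/21
  #  t=10: 1 at risk, 1 event -> 0
  k3 <- km_curve(c(6, 6, 6, 6, 7, 9, 10), c(1, 1, 1, 0, 1, 0, 1))
  expect_equal(k3$surv[k3$time == 6], 4 / 7)
  expect_equal(k3$surv[k3$time == 7], 8 / 21)
  expect_equal(k3$surv[k3$time == 10], 0)
  expect_true(all(diff(k3$surv) <= 0))
  # Greenwood SE at the first step: S * sqrt(d / (n (n - d)))
  expect_equal(k3$se[k3$time == 6], (4 / 7) * sqrt(3 / (7 * 4)),
               tolerance = 1e-10)
})

test_that("log-rank matches an independent O-E/V oracle and is symmetric", {
  set.seed(26)
  for (i in 1:5) {
    times <- c(sample(1:20, 5, TRUE), sample(1:12, 5, TRUE))
    events <- rbinom(10, 1, 0.8)
    g <- rep(c(0, 1), each = 5)
    if (sum(events) == 0) next
    lr <- logrank_test(g, times, events)
    expect_equal(lr$chisq, brute_logrank(g, times, events),
                 tolerance = 1e-10)
    expect_equal(logrank_test(1 - g, times, events)$chisq, lr$chisq,
                 tolerance = 1e-12)
  }
})

test_that("log-rank type-I error is near nominal under a null generator", {
  set.seed(27)
  rej <- mean(replicate(1500, {
    times <- rexp(80, 0.02)
    cens <- runif(80, 0, 60)
    obs <- pmin(times, cens)
    ev <- as.integer(times <= cens)
    logrank_test(rep(c(0, 1), 40), obs, ev)$p < 0.05
  }))
  expect_equal(rej, 0.05, tolerance = 0.017 / 0.05)   # 3 MC SEs
})

test_that("recurrence analysis separates arms under a circularity-driven hazard", {
  coh <- generate_feature_cohort(n_per_group = 400, seed = 28)
  pp <- survival_sim_params(baseline_hazard = 0.01, circularity_coef = 40,
                            censor_min = 1, censor_max = 200, seed = 28)
  ss <- attach_survival(coh, pp)
  ra <- recurrence_analysis(ss, cutoff = median(ss$circularity))
  expect_lt(ra$overall$logrank$p, 0.01)
  # high-circularity arm sits below the low arm at a common late time
  t_star <- min(max(ra$overall$km_low$time), max(ra$overall$km_high$time)) / 2
  s_at <- function(km, t) {
    i <- km$time <= t
    if (!any(i)) 1 else km$surv[max(which(i))]
  }
  expect_lt(s_at(ra$overall$km_high, t_star), s_at(ra$overall$km_low, t_star))
  expect_true(length(ra$strata) >= 1)
  # a cutoff beyond the data leaves one arm: explicit error
  expect_error(recurrence_analysis(ss, cutoff = 2), "single arm")
})

test_that("null hazards give non-significant recurrence comparisons at nominal rate", {
  coh <- generate_feature_cohort(n_per_group = 150, seed = 29)
  p0 <- survival_sim_params(baseline_hazard = 0.01, circularity_coef = 0,
                            censor_min = 1, censor_max = 200, seed = 29)
  ss <- attach_survival(coh, p0)
  ra <- recurrence_analysis(ss, cutoff = median(ss$circularity))
  expect_gt(ra$overall$logrank$p, 0.001)
})
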