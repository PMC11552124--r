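# Hand-evaluated linear-combination oracles for the shipped models at the
# reference group means:
#   FA model at FA means (area 14.9, min caliper 3.30, eccentricity 0.81):
#     -197.039 - 3.881*14.9 + 35.176*3.30 + 172.063*0.81 = 0.58593
#   FA model at benign-PT means (17.02, 3.51, 0.80)      = -1.97546
#   grading model at benign-PT means (perimeter 17.35, circularity 0.69,
#     min caliper 3.51, eccentricity 0.80)               = -1.44503
#   grading model at malignant means (18.18, 0.69, 3.77, 0.78) = 0.19482

test_that("shipped models reproduce hand-computed scores at group means", {
  fa <- fa_vs_benign_pt_model()
  gr <- pt_grading_model()
  expect_equal(nuclear_morphology_score(
    c(area_um2 = 14.9, min_caliper_um = 3.30, eccentricity = 0.81), fa),
    0.586, tolerance = 1e-3)
  expect_equal(nuclear_morphology_score(
    c(area_um2 = 17.02, min_caliper_um = 3.51, eccentricity = 0.80), fa),
    -1.975, tolerance = 1e-3)
  expect_equal(nuclear_morphology_score(
    c(perimeter_um = 17.35, circularity = 0.69, min_caliper_um = 3.51,
      eccentricity = 0.80), gr),
    -1.445, tolerance = 1e-3)
  expect_equal(nuclear_morphology_score(
    c(perimeter_um = 18.18, circularity = 0.69, min_caliper_um = 3.77,
      eccentricity = 0.78), gr),
    0.195, tolerance = 1e-3)
  # all-zero features -> intercept
  expect_equal(nuclear_morphology_score(
    c(perimeter_um = 0, circularity = 0, min_caliper_um = 0,
      eccentricity = 0), gr), gr$intercept)
  expect_error(nuclear_morphology_score(c(area_um2 = 1), gr),
               "perimeter_um")
})

test_that("classification lands each group mean on the expected side of the cutoff", {
  gr <- pt_grading_model()
  expect_equal(classify_score(-1.445, gr), "benign-like")
  expect_equal(classify_score(0.195, gr), "borderline/malignant-like")
  # tie rule: exactly at the cutoff -> high class
  expect_equal(classify_score(gr$cutoff, gr), gr$labels[2])
  fa <- fa_vs_benign_pt_model()
  expect_equal(classify_score(0.586, fa), "FA-like")
  expect_equal(classify_score(-1.975, fa), "benign PT-like")
})

test_that("scores are monotone in each feature with the coefficient sign", {
  set.seed(10)
  for (m in list(pt_grading_model(), fa_vs_benign_pt_model())) {
    base <- runif(length(m$coefficients), 0, 20)
    names(base) <- names(m$coefficients)
    s0 <- nuclear_morphology_score(base, m)
    for (f in names(m$coefficients)) {
      up <- base; up[f] <- up[f] + 0.5
      expect_equal(sign(nuclear_morphology_score(up, m) - s0),
                   sign(m$coefficients[[f]]))
    }
  }
})

test_that("score model JSON round trip preserves scores to 1e-12", {
  m <- pt_grading_model()
  p <- tempfile(fileext = ".json")
  write_score_model(m, p)
  m2 <- read_score_model(p)
  set.seed(11)
  x <- data.frame(perimeter_um = runif(20, 15, 20),
                  circularity = runif(20, 0.6, 0.75),
                  min_caliper_um = runif(20, 3, 4),
                  eccentricity = runif(20, 0.7, 0.85))
  expect_equal(nuclear_morphology_score(x, m2),
               nuclear_morphology_score(x, m), tolerance = 1e-12)
  unlink(p)
  expect_error(score_model("bad", 0, c(not_a_feature = 1), 0),
               "unknown feature")
})

test_that("contingency metrics reproduce the printed diagnostic percentages", {
  tab <- rbind(low = c(benign = 117, borderline = 28, malignant = 6),
               high = c(benign = 32, borderline = 38, malignant = 20))
  m1 <- contingency_metrics(tab, "benign", c("borderline", "malignant"))
  expect_equal(m1$within_low, 100 * 117 / 151)
  expect_equal(m1$within_low_printed, 77.4)    # truncation: 77.48 -> 77.4
  expect_equal(m1$within_high_printed, 64.4)
  m2 <- contingency_metrics(tab, c("benign", "borderline"),
                            c("benign", "borderline"))
  expect_equal(m2$within_low_printed, 96.0)    # 145/151
  expect_equal(m2$within_high_printed, 77.7)   # 70/90, truncated from 77.77
  # conventional column-wise metrics, clearly separate figures
  expect_equal(m1$sensitivity, 100 * 117 / 149)
  expect_equal(m1$specificity, 100 * 58 / 92)
  fa_tab <- rbind(low = c(FA = 6, benign = 104),
                  high = c(FA = 53, benign = 45))
  m3 <- contingency_metrics(fa_tab, "benign", "FA")
  expect_equal(round(m3$sensitivity), 70)      # 104/149
  expect_equal(round(m3$specificity), 90)      # 53/59
  # rounding mode on request
  m4 <- contingency_metrics(tab, "benign", c("borderline", "malignant"),
                            method = "round")
  expect_equal(m4$within_low_printed, 77.5)
})

test_that("contingency metrics are invariant to column permutation and reject empty rows", {
  tab <- rbind(low = c(a = 10, b = 2, c = 1),
               high = c(a = 3, b = 8, c = 9))
  m <- contingency_metrics(tab, "a", c("b", "c"))
  mp <- contingency_metrics(tab[, c(3, 1, 2)], "a", c("b", "c"))
  expect_equal(mp, m)
  single <- rbind(low = c(a = 10), high = c(a = 0))
  expect_error(contingency_metrics(single, "a", "a"), "empty high row")
})

test_that("score_cohort cross-tabulates classes against diagnosis labels", {
  coh <- generate_feature_cohort(n_per_group = 40, seed = 12)
  res <- score_cohort(coh, fa_vs_benign_pt_model())
  expect_equal(sum(res$table), nrow(coh))
  expect_equal(colnames(res$table),
               c("FA", "benign PT", "borderline PT", "malignant PT"))
  expect_equal(nrow(res$scored), nrow(coh))
  # at the degenerate zero-SD limit every case sits at its group mean, so
  # classification is exact: FA high (FA-like side), benign PT low
  g0 <- fel_reference_groups()
  g0[, grep("_sd$", names(g0))] <- 0
  c0 <- generate_feature_cohort(groups = g0, n_per_group = 10, seed = 1)
  r0 <- score_cohort(c0, fa_vs_benign_pt_model())
  expect_equal(unname(r0$table["high", "FA"]), 10)
  expect_equal(unname(r0$table["low", "benign PT"]), 10)
})
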