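#' Reference per-group feature distributions
#'
#' Group-level mean and SD of the six per-case nuclear features for the
#' four FEL diagnostic groups (fibroadenoma; benign, borderline and
#' malignant phyllodes tumour), together with the group sizes, used as
#' simulation targets by \code{\link{generate_feature_cohort}}. Units:
#' area um^2, perimeter and calipers um, circularity and eccentricity
#' dimensionless.
#'
#' @return data.frame with columns \code{group, n} and
#'   \code{<feature>_mean}, \code{<feature>_sd} for each of
#'   \code{\link{nuclear_feature_names}}.
#' @export
fel_reference_groups <- function() {
  g <- data.frame(
    group = c("FA", "benign PT", "borderline PT", "malignant PT"),
    n = c(59L, 149L, 66L, 26L),
    area_um2_mean = c(14.9, 17.02, 17.60, 19.00),
    area_um2_sd = c(1.48, 2.06, 2.20, 3.25),
    perimeter_um_mean = c(16.48, 17.35, 17.53, 18.18),
    perimeter_um_sd = c(0.73, 0.99, 1.01, 1.47),
    circularity_mean = c(0.67, 0.69, 0.69, 0.69),
    circularity_sd = c(0.01, 0.02, 0.02, 0.02),
    max_caliper_um_mean = c(6.33, 6.65, 6.65, 6.84),
    max_caliper_um_sd = c(0.27, 0.37, 0.37, 0.57),
    min_caliper_um_mean = c(3.30, 3.51, 3.62, 3.77),
    min_caliper_um_sd = c(0.19, 0.25, 0.26, 0.34),
    eccentricity_mean = c(0.81, 0.80, 0.78, 0.78),
    eccentricity_sd = c(0.01, 0.02, 0.02, 0.02))
  g
}

#' Default between-case feature correlation model
#'
#' The reference group summaries carry no covariance information, so the
#' generator adopts a stated assumption: the four size features (area,
#' perimeter, max and min caliper) are positively correlated (0.6), shape
#' features circularity and eccentricity are negatively correlated with
#' each other (-0.5), and size and shape blocks are independent. The matrix
#' is positive definite by construction; any user-supplied replacement is
#' checked.
#'
#' @param size_rho,shape_rho block correlations (defaults 0.6 and -0.5).
#' @return 6 x 6 correlation matrix, dimnames =
#'   \code{\link{nuclear_feature_names}}.
#' @export
default_feature_correlation <- function(size_rho = 0.6, shape_rho = -0.5) {
  f <- nuclear_feature_names()
  R <- diag(6)
  dimnames(R) <- list(f, f)
  size <- c("area_um2", "perimeter_um", "max_caliper_um", "min_caliper_um")
  R[size, size] <- size_rho
  R["circularity", "eccentricity"] <- shape_rho
  R["eccentricity", "circularity"] <- shape_rho
  diag(R) <- 1
  R
}

#' Generate a synthetic per-case feature cohort
#'
#' Draws per-case mean features from a multivariate normal per group, with
#' the supplied group means/SDs and a common between-feature correlation
#' model, emulating the statistical structure of a real FEL cohort.
#' Deterministic for a fixed seed; sample means converge to the group means
#' at rate SD/sqrt(n).
#'
#' @param groups data.frame in the \code{\link{fel_reference_groups}}
#'   schema (the default).
#' @param n_per_group optional integer vector recycled over groups,
#'   overriding \code{groups$n}.
#' @param correlation 6 x 6 positive-definite correlation matrix (default
#'   \code{\link{default_feature_correlation}()}).
#' @param seed integer RNG seed (required).
#' @return data.frame of case records: \code{case_id, group} plus the six
#'   feature columns.
#' @examples
#' coh <- generate_feature_cohort(seed = 1)
#' aggregate(area_um2 ~ group, coh, mean)
#' @export
generate_feature_cohort <- function(groups = fel_reference_groups(),
                                    n_per_group = NULL,
                                    correlation = default_feature_correlation(),
                                    seed) {
  if (missing(seed)) stop("a seed is required for reproducible cohorts")
  f <- nuclear_feature_names()
  stopifnot(all(paste0(f, "_mean") %in% names(groups)),
            all(paste0(f, "_sd") %in% names(groups)))
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive definite")
  ns <- if (is.null(n_per_group)) groups$n else
    rep_len(n_per_group, nrow(groups))
  if (any(ns < 2)) stop("need at least 2 cases per group")
  set.seed(as.integer(seed))
  out <- vector("list", nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    mu <- as.numeric(groups[gi, paste0(f, "_mean")])
    sd <- as.numeric(groups[gi, paste0(f, "_sd")])
    if (any(sd < 0)) stop("negative SD")
    Sigma <- diag(sd) %*% correlation %*% diag(sd)
    X <- MASS::mvrnorm(ns[gi], mu = mu, Sigma = Sigma)
    colnames(X) <- f
    out[[gi]] <- cbind(data.frame(group = groups$group[gi]),
                       as.data.frame(X))
  }
  res <- do.call(rbind, out)
  res <- cbind(case_id = sprintf("case_%04d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}

#' Survival-simulation parameters
#'
#' @param baseline_hazard events per month for a case at the cohort-mean
#'   circularity (default 0.0023/month, matching roughly 21 events in 169
#'   cases over a mean 55-month follow-up).
#' @param circularity_coef log-hazard per unit circularity (default 25,
#'   i.e. ~0.5 log-hazard per 0.02 circularity SD; 0 gives a null cohort).
#' @param censor_min,censor_max uniform censoring-time bounds in months
#'   (defaults 1 and 110, mean ~55).
#' @param seed integer RNG seed.
#' @return a \code{survival_sim_params} list.
#' @export
survival_sim_params <- function(baseline_hazard = 0.0023,
                                circularity_coef = 25,
                                censor_min = 1, censor_max = 110, seed = 1) {
  stopifnot(baseline_hazard > 0, censor_min >= 0,
            censor_max >= censor_min)
  structure(list(baseline_hazard = baseline_hazard,
                 circularity_coef = circularity_coef,
                 censor_min = censor_min, censor_max = censor_max,
                 seed = seed),
            class = "survival_sim_params")
}

#' Attach simulated event-free-survival outcomes to a cohort
#'
#' Event times are exponential with a proportional-hazards dependence on
#' circularity, \code{hazard = baseline * exp(coef * (circ - mean(circ)))};
#' observed time is the minimum of event and (uniform) censoring time, with
#' the event flag set accordingly. Exponential hazards keep group medians
#' analytic (\code{log(2)/hazard}).
#'
#' @param cases cohort data.frame with a \code{circularity} column.
#' @param params a \code{\link{survival_sim_params}} object.
#' @return \code{cases} with \code{time_months} and \code{event} (0/1)
#'   appended.
#' @export
attach_survival <- function(cases, params = survival_sim_params()) {
  stopifnot(inherits(params, "survival_sim_params"))
  if (!"circularity" %in% names(cases))
    stop("every case needs a circularity value")
  set.seed(as.integer(params$seed))
  n <- nrow(cases)
  haz <- params$baseline_hazard *
    exp(params$circularity_coef * (cases$circularity -
                                     mean(cases$circularity)))
  t_event <- stats::rexp(n, rate = haz)
  t_cens <- stats::runif(n, params$censor_min, params$censor_max)
  cases$time_months <- pmin(t_event, t_cens)
  cases$event <- as.integer(t_event <= t_cens)
  cases
}

#' Write / read a cohort as CSV
#'
#' Plain-text cohort exchange format: \code{case_id, group}, the six
#' feature columns, and \code{time_months, event} when present.
#'
#' @param cases cohort data.frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
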