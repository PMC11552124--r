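#' Diagnostic score models
#'
#' A score model is a linear predictor over per-case mean nuclear features,
#' \deqn{score = \beta_0 + \sum_i \beta_i x_i,} with a decision cutoff and
#' class labels for the two sides. Coefficients apply to features in raw
#' calibrated units (um^2, um, dimensionless) with no standardisation.
#'
#' @param name model name.
#' @param intercept \eqn{\beta_0}.
#' @param coefficients named numeric vector; names must be a subset of
#'   \code{\link{nuclear_feature_names}}.
#' @param cutoff finite decision threshold on the score.
#' @param labels character length-2, labels for score \code{< cutoff} and
#'   \code{>= cutoff} (in that order).
#' @return object of class \code{score_model}.
#' @export
score_model <- function(name, intercept, coefficients, cutoff,
                        labels = c("low", "high")) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.finite(cutoff), length(labels) == 2)
  bad <- setdiff(names(coefficients), nuclear_feature_names())
  if (length(bad))
    stop("unknown feature(s) in coefficients: ", paste(bad, collapse = ", "))
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, cutoff = cutoff,
                 labels = labels),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model '%s': cutoff %.4f (< -> '%s', >= -> '%s')\n",
              x$name, x$cutoff, x$labels[1], x$labels[2]))
  cat(sprintf("  intercept %.4f\n", x$intercept))
  for (f in names(x$coefficients))
    cat(sprintf("  %-16s %+.4f\n", f, x$coefficients[f]))
  invisible(x)
}

#' Built-in score models
#'
#' The three fitted models shipped with the package:
#' \code{pt_grading_model()} separates benign from borderline/malignant PT
#' (perimeter, circularity, min caliper, eccentricity; cutoff -0.2008),
#' \code{fa_vs_benign_pt_model()} separates FA from benign PT (area, min
#' caliper, eccentricity; cutoff -1.0596, scores at or above the cutoff on
#' the FA side), and \code{circularity_recurrence_model()} is the
#' single-feature recurrence classifier (circularity, cutoff 0.698).
#' Definitions are read from the JSON files under
#' \code{inst/extdata}, the same files \code{\link{read_score_model}}
#' consumes.
#'
#' @return a \code{\link{score_model}}.
#' @export
pt_grading_model <- function() builtin_model("pt_grading")

#' @rdname pt_grading_model
#' @export
fa_vs_benign_pt_model <- function() builtin_model("fa_vs_benign_pt")

#' @rdname pt_grading_model
#' @export
circularity_recurrence_model <- function() builtin_model("circularity_recurrence")

builtin_model <- function(name) {
  path <- system.file("extdata", paste0(name, "_model.json"),
                      package = "felmorph", mustWork = TRUE)
  read_score_model(path)
}

#' Read or write a score model as JSON
#'
#' @param path JSON file path.
#' @param model a \code{\link{score_model}}.
#' @export
read_score_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  score_model(j$name, j$intercept, unlist(j$coefficients), j$cutoff,
              j$labels)
}

#' @rdname read_score_model
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  jsonlite::write_json(
    list(name = model$name, intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         cutoff = model$cutoff, labels = model$labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Nuclear morphology score of one or more cases
#'
#' The exact linear combination \eqn{\beta_0 + \sum \beta_i x_i} over the
#' per-case mean features named by the model.
#'
#' @param features named numeric vector, or a data.frame with one row per
#'   case containing the model's feature columns.
#' @param model a \code{\link{score_model}}.
#' @return numeric score vector.
#' @examples
#' m <- score_model("demo", 1, c(area_um2 = 2), 0)
#' nuclear_morphology_score(c(area_um2 = 3), m)   # 7
#' @export
nuclear_morphology_score <- function(features, model) {
  stopifnot(inherits(model, "score_model"))
  need <- names(model$coefficients)
  if (is.data.frame(features)) {
    miss <- setdiff(need, names(features))
    if (length(miss))
      stop("missing feature(s): ", paste(miss, collapse = ", "))
    X <- as.matrix(features[, need, drop = FALSE])
  } else {
    miss <- setdiff(need, names(features))
    if (length(miss))
      stop("missing feature(s): ", paste(miss, collapse = ", "))
    X <- matrix(features[need], 1, dimnames = list(NULL, need))
  }
  if (any(!is.finite(X))) stop("non-finite feature value")
  drop(model$intercept + X %*% model$coefficients[need])
}

#' Classify a score against the model cutoff
#'
#' Scores at or above the cutoff take the second (high) label; the tie at
#' exactly the cutoff goes to the high side.
#'
#' @param score numeric score vector (finite).
#' @param model a \code{\link{score_model}}.
#' @return character vector of class labels.
#' @export
classify_score <- function(score, model) {
  stopifnot(inherits(model, "score_model"), all(is.finite(score)))
  ifelse(score >= model$cutoff, model$labels[2], model$labels[1])
}

#' Diagnostic metrics of a score-class by diagnosis contingency table
#'
#' Two families of percentages from a 2 x k table of score class (rows
#' \code{low}, \code{high}) by diagnosis (columns):
#' \itemize{
#'   \item within-row fractions: of cases called low (high), the
#'     percentage whose diagnosis is in the designated low-side (high-side)
#'     column set. These are predictive-value-style figures; printed to one
#'     decimal they are truncated toward zero by default
#'     (\code{method = "truncate"}), with conventional rounding available.
#'   \item conventional column-wise sensitivity/specificity:
#'     \code{sensitivity} = percentage of designated low-side diagnoses
#'     that were called low; \code{specificity} = percentage of designated
#'     high-side diagnoses that were called high.
#' }
#'
#' @param tab 2 x k numeric matrix of non-negative counts; rows
#'   \code{c("low", "high")}, named columns.
#' @param low_designated,high_designated character vectors of column names
#'   designated correct for the low and high row respectively.
#' @param digits decimals for the printed within-row values (default 1).
#' @param method \code{"truncate"} (default) or \code{"round"} for the
#'   printed within-row values.
#' @return list: \code{within_low}, \code{within_high} (raw percent),
#'   \code{within_low_printed}, \code{within_high_printed},
#'   \code{sensitivity}, \code{specificity} (raw percent, column-wise).
#' @examples
#' tab <- rbind(low = c(benign = 117, borderline = 28, malignant = 6),
#'              high = c(benign = 32, borderline = 38, malignant = 20))
#' contingency_metrics(tab, "benign", c("borderline", "malignant"))
#' @export
contingency_metrics <- function(tab, low_designated, high_designated,
                                digits = 1,
                                method = c("truncate", "round")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, all(tab >= 0), sum(tab) > 0,
            all(low_designated %in% colnames(tab)),
            all(high_designated %in% colnames(tab)))
  rn <- rownames(tab)
  if (is.null(rn)) rn <- c("low", "high")
  low <- tab[match("low", rn), ]
  high <- tab[match("high", rn), ]
  if (sum(low) == 0) stop("empty low row: within-low fraction undefined")
  if (sum(high) == 0) stop("empty high row: within-high fraction undefined")
  wl <- 100 * sum(low[low_designated]) / sum(low)
  wh <- 100 * sum(high[high_designated]) / sum(high)
  fmt <- function(x) {
    if (method == "truncate") trunc(x * 10^digits) / 10^digits
    else round(x, digits)
  }
  col_tot_low <- colSums(tab)[low_designated]
  col_tot_high <- colSums(tab)[high_designated]
  sens <- if (sum(col_tot_low) > 0)
    100 * sum(low[low_designated]) / sum(col_tot_low) else NA_real_
  spec <- if (sum(col_tot_high) > 0)
    100 * sum(high[high_designated]) / sum(col_tot_high) else NA_real_
  list(within_low = wl, within_high = wh,
       within_low_printed = fmt(wl), within_high_printed = fmt(wh),
       sensitivity = sens, specificity = spec)
}

#' Score a cohort and cross-tabulate against diagnosis
#'
#' Applies a score model to a cohort data.frame, classifies each case, and
#' builds the 2 x k contingency table of score class by diagnosis label.
#'
#' @param cases data.frame with the model's feature columns and a
#'   diagnosis column.
#' @param model a \code{\link{score_model}}.
#' @param label_col name of the diagnosis column (default \code{"group"}).
#' @return list: \code{scored} (cases plus \code{score}, \code{class}) and
#'   \code{table} (counts, rows \code{low}/\code{high}).
#' @export
score_cohort <- function(cases, model, label_col = "group") {
  s <- nuclear_morphology_score(cases, model)
  cl <- classify_score(s, model)
  scored <- cbind(cases, score = s, class = cl)
  lvl <- unique(cases[[label_col]])
  tab <- rbind(
    low = sapply(lvl, function(g)
      sum(cl == model$labels[1] & cases[[label_col]] == g)),
    high = sapply(lvl, function(g)
      sum(cl == model$labels[2] & cases[[label_col]] == g)))
  colnames(tab) <- lvl
  list(scored = scored, table = tab)
}
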