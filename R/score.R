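#' LASSO feature selection for the methylation score
#'
#' Fits an L1-penalized logistic regression of case/control status on the
#' candidate markers' MEPM values. The penalty is chosen by k-fold
#' cross-validation (default 10 folds, stratified by class) with the
#' one-standard-error rule; markers with nonzero coefficients at that
#' penalty are returned. Values are standardized internally for the
#' penalized fit.
#'
#' @param x `meth_matrix` of the training plasma cohort.
#' @param labels Named binary vector (1 = case) covering all samples, or
#'   NULL to derive from the sample sheet (condition != `"normal"`).
#' @param candidate_markers Site ids to offer to the LASSO.
#' @param seed Integer seed (fold assignment), makes selection
#'   deterministic.
#' @param nfolds Number of cross-validation folds (default 10).
#' @param rule `"1se"` (default) or `"min"` penalty choice.
#' @return Character vector of selected marker ids (possibly empty).
#' @export
lasso_select_features <- function(x, labels = NULL, candidate_markers,
                                  seed, nfolds = 10,
                                  rule = c("1se", "min")) {
  rule <- match.arg(rule)
  validate_meth_matrix(x)
  if (is.null(labels)) {
    labels <- stats::setNames(
      as.integer(x$samples$condition != "normal"), x$samples$sample_id)
  }
  labels <- labels[x$samples$sample_id]
  if (length(unique(labels)) < 2 || min(table(labels)) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  if (length(candidate_markers) < 2) {
    stop("need at least 2 candidate markers", call. = FALSE)
  }
  xm <- x$values[, candidate_markers, drop = FALSE]
  foldid <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      f[i] <- sample(rep_len(seq_len(nfolds), length(i)))
    }
    f
  })
  cv <- glmnet::cv.glmnet(xm, labels, family = "binomial", alpha = 1,
                          standardize = TRUE, foldid = foldid,
                          type.measure = "deviance")
  lam <- if (rule == "1se") cv$lambda.1se else cv$lambda.min
  cf <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))
  sel <- rownames(cf)[-1][cf[-1, 1] != 0]
  sel
}

#' Fit the logistic methylation-score model
#'
#' Unpenalized logistic refit of case/control status on the selected
#' markers' raw MEPM values. If the refit separates the classes perfectly
#' (coefficients diverge), the fit falls back to a lightly
#' ridge-stabilized logistic model and flags this in `training_meta`.
#'
#' @param x `meth_matrix` of the training cohort.
#' @param labels Named binary vector (1 = case), or NULL to derive from
#'   the sample sheet.
#' @param selected_markers Non-empty character vector of marker ids.
#' @param ridge_lambda L2 penalty used by the separation fallback
#'   (default 1e-3).
#' @return List of class `score_model` with `marker_ids`, `coefficients`
#'   (named), `intercept` and `training_meta`.
#' @export
fit_score_model <- function(x, labels = NULL, selected_markers,
                            ridge_lambda = 1e-3) {
  validate_meth_matrix(x)
  if (length(selected_markers) == 0) {
    stop("selected_markers must be non-empty", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- stats::setNames(
      as.integer(x$samples$condition != "normal"), x$samples$sample_id)
  }
  labels <- labels[x$samples$sample_id]
  xm <- x$values[, selected_markers, drop = FALSE]
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, xm), labels,
                   family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || any(abs(fit$coefficients) > 1e3) ||
      anyNA(fit$coefficients)) {
    # ridge-stabilized logistic fit for (near-)separated training data
    rfit <- glmnet::glmnet(xm, labels, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = TRUE)
    cf <- as.matrix(stats::coef(rfit))[, 1]
    coefs <- cf[-1]
    intercept <- cf[1]
    separated <- TRUE
  } else {
    coefs <- fit$coefficients[-1]
    intercept <- fit$coefficients[1]
  }
  structure(list(marker_ids = selected_markers,
                 coefficients = stats::setNames(coefs, selected_markers),
                 intercept = unname(intercept),
                 training_meta = list(n = length(labels),
                                      prevalence = mean(labels),
                                      ridge_stabilized = separated,
                                      ridge_lambda =
                                        if (separated) ridge_lambda else NA)),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score_model: %d markers, intercept %.4g%s\n",
              length(x$marker_ids), x$intercept,
              if (isTRUE(x$training_meta$ridge_stabilized))
                " (ridge-stabilized)" else ""))
  invisible(x)
}

#' Methylation score of one sample
#'
#' The linear predictor `intercept + sum(Coef_i * A_i)` where `A_i` is the
#' sample's MEPM value at marker i. The intercept is included so that the
#' zero threshold of [waterfall_classify()] coincides with the logistic
#' decision boundary.
#'
#' @param values Named numeric vector covering all model markers.
#' @param model A [fit_score_model()] result.
#' @return Numeric score.
#' @export
methylation_score <- function(values, model) {
  miss <- setdiff(model$marker_ids, names(values))
  if (length(miss)) {
    stop("sample lacks model marker(s): ",
         paste(utils::head(miss, 3), collapse = ", "), call. = FALSE)
  }
  model$intercept +
    sum(model$coefficients * values[model$marker_ids])
}

#' Waterfall classification by methylation score
#'
#' Samples with score strictly above zero are called positive (patients);
#' zero or below is negative (the boundary favors specificity). The
#' result is ordered by descending score for waterfall display.
#'
#' @param scores Named numeric vector of methylation scores.
#' @return Data frame with `sample_id`, `score` and `call`
#'   (`"positive"`/`"negative"`), sorted by descending score.
#' @export
waterfall_classify <- function(scores) {
  if (length(scores) == 0) {
    return(data.frame(sample_id = character(), score = numeric(),
                      call = character(), stringsAsFactors = FALSE))
  }
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  out <- data.frame(sample_id = ids, score = as.numeric(scores),
                    call = ifelse(scores > 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Late-stage compatibility flag from a panel evaluation
#'
#' On the PAC panel, only counts above 8 positive markers or a total
#' positive methylation above 150 MEPM are seen in stage III/IV disease;
#' a sample exceeding either bound is flagged late-stage compatible,
#' anything else is indeterminate (early and late ranges overlap below
#' the bounds).
#'
#' @param evaluation A `panel_evaluation` (see [evaluate_panel()]).
#' @param count_bound Positive-count bound (default 8, strict).
#' @param total_bound Total-methylation bound in MEPM
#'   (default 150, strict).
#' @return `"late_stage_compatible"` or `"indeterminate"`.
#' @export
stage_flag <- function(evaluation, count_bound = 8, total_bound = 150) {
  stopifnot(inherits(evaluation, "panel_evaluation"))
  if (evaluation$positive_count > count_bound ||
      evaluation$total_methylation > total_bound) {
    "late_stage_compatible"
  } else {
    "indeterminate"
  }
}
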