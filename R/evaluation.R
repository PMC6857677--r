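# Hold-out evaluation: confusion matrices, overall and balanced accuracy,
# and index-vs-probability curves.

#' Confusion matrix of trophic state predictions
#'
#' @param actual Observed trophic states.
#' @param predicted Predicted trophic states, same length.
#' @return 4x4 integer matrix of counts; rows are the actual state, columns
#'   the predicted state.
#' @export
confusion_matrix <- function(actual, predicted) {
  actual <- as_trophic_state(actual)
  predicted <- as_trophic_state(predicted)
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have the same length", call. = FALSE)
  }
  if (length(actual) < 1) stop("need at least one observation", call. = FALSE)
  cm <- table(actual = actual, predicted = predicted)
  m <- matrix(as.integer(cm), 4, 4,
              dimnames = list(actual = trophic_levels(),
                              predicted = trophic_levels()))
  m
}

#' Overall accuracy
#'
#' Proportion of lakes whose predicted state equals the observed state:
#' trace of the confusion matrix over its total.
#'
#' @param cm Confusion matrix (rows actual, columns predicted).
#' @return Proportion in \[0, 1\].
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Balanced accuracy for one trophic state
#'
#' One-vs-rest mean of sensitivity (true-positive rate, from the class's
#' row) and specificity (true-negative rate, from the complement).  Robust
#' to class imbalance, unlike overall accuracy.
#'
#' @param cm Confusion matrix (rows actual, columns predicted).
#' @param k The state of interest (code 1--4, name, or factor).
#' @return Proportion in \[0, 1\].
#' @export
balanced_accuracy <- function(cm, k) {
  k <- .state_code(k)
  stopifnot(length(k) == 1, !is.na(k))
  if (sum(cm[k, ]) == 0) {
    stop("balanced accuracy undefined: no actual instances of class '",
         trophic_levels()[k], "'", call. = FALSE)
  }
  sens <- cm[k, k] / sum(cm[k, ])
  tn <- sum(cm[-k, -k])
  fp <- sum(cm[-k, k])
  spec <- tn / (tn + fp)
  (sens + spec) / 2
}

# full metrics bundle from a confusion matrix
.metrics_from_cm <- function(cm) {
  lv <- trophic_levels()
  sens <- spec <- bal <- stats::setNames(rep(NA_real_, 4), lv)
  for (k in 1:4) {
    if (sum(cm[k, ]) > 0) {
      sens[k] <- cm[k, k] / sum(cm[k, ])
      tn <- sum(cm[-k, -k]); fp <- sum(cm[-k, k])
      spec[k] <- tn / (tn + fp)
      bal[k] <- (sens[k] + spec[k]) / 2
    }
  }
  structure(list(confusion = cm,
                 overall_accuracy = overall_accuracy(cm),
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = bal, n_eval = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Evaluation on n =", x$n_eval, "lakes\n")
  cat("Overall accuracy:", round(x$overall_accuracy, 2), "\n")
  tab <- data.frame(sensitivity = round(x$sensitivity, 2),
                    specificity = round(x$specificity, 2),
                    balanced = round(x$balanced_accuracy, 2))
  print(tab)
  invisible(x)
}

#' Evaluate a fitted model on a hold-out set
#'
#' Standardizes the evaluation lakes with the model's training spec,
#' classifies each lake by the interval rule on its index, and reports
#' the confusion matrix, overall accuracy and per-class balanced accuracy.
#' The evaluation set must be disjoint from training; overlapping lake ids
#' (when the model records them) raise a warning.  A class with no actual
#' instances gets `NA` metrics; the others are still computed.
#'
#' @param model A `trophic_model`.
#' @param eval_set Labeled lake data.frame (`trophic_state` present).
#' @return Object of class `metrics_report`.
#' @export
evaluate_holdout <- function(model, eval_set) {
  stopifnot(inherits(model, "trophic_model"))
  if (!("trophic_state" %in% names(eval_set))) {
    stop("evaluation set must carry observed trophic_state", call. = FALSE)
  }
  train_ids <- model$meta$training_ids
  if (!is.null(train_ids) && any(eval_set$lake_id %in% train_ids)) {
    warning("evaluation set overlaps the training lakes (",
            sum(eval_set$lake_id %in% train_ids), " shared ids)",
            call. = FALSE)
  }
  pred <- predict_lakes(model, eval_set)
  cm <- confusion_matrix(eval_set$trophic_state, pred$predicted_class)
  .metrics_from_cm(cm)
}

#' Class probability curves along the trophic index
#'
#' Tabulates the four class probabilities on a grid of index values: the
#' numeric content of the classic index-versus-probability figure, showing
#' how class membership shifts smoothly across the cutpoints.
#'
#' @param params `polr_params`.
#' @param grid Numeric vector of index values (default \[-8, 8\] by 0.1).
#' @return data.frame with columns `tsi`, `p_oligotrophic`,
#'   `p_mesotrophic`, `p_eutrophic`, `p_hypereutrophic`.
#' @export
probability_curves <- function(params, grid = seq(-8, 8, by = 0.1)) {
  if (any(!is.finite(grid))) stop("grid must be finite", call. = FALSE)
  probs <- class_probabilities(grid, params)
  colnames(probs) <- paste0("p_", trophic_levels())
  data.frame(tsi = grid, probs, row.names = NULL)
}

#' Write a metrics report to JSON and CSV
#'
#' @param report A `metrics_report`.
#' @param json_path Path for the JSON metrics (optional).
#' @param csv_path Path for the confusion-matrix CSV, rows actual and
#'   columns predicted (optional).
#' @param seed,version Metadata recorded in the JSON report.
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL,
                          seed = NULL, version = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(json_path)) {
    obj <- list(overall_accuracy = report$overall_accuracy,
                sensitivity = as.list(report$sensitivity),
                specificity = as.list(report$specificity),
                balanced_accuracy = as.list(report$balanced_accuracy),
                n_eval = report$n_eval,
                meta = list(version = version %||%
                              as.character(utils::packageVersion("trophicstate")),
                            seed = seed))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = I(17),
                         na = "null", null = "null")
  }
  if (!is.null(csv_path)) {
    out <- as.data.frame(report$confusion)
    out <- cbind(actual = rownames(report$confusion),
                 as.data.frame.matrix(report$confusion))
    utils::write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
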