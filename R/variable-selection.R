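# Random-forest variable selection: permutation importance (%IncMSE) on an
# out-of-bag basis, then the minimal predictor subset by an error-increment
# rule on nested forests.
#
# The forest treats the 4-level ordinal response as numeric 1..4 in
# regression mode: importance is reported as percent increase in mean
# squared error, which has no analogue in a classification forest.  Tree
# induction itself is delegated to the randomForest package; this module's
# contribution is the ranking and the selection rule.

#' Rank candidate predictors by random-forest importance
#'
#' Grows a regression-mode random forest on all candidate features (ordinal
#' response coded 1--4) and ranks them by out-of-bag permutation importance,
#' the percent increase in mean squared error when a feature is permuted.
#' Zero-variance features are excluded with a warning.  Deterministic for a
#' fixed seed.
#'
#' @param features data.frame or matrix of candidate predictors.
#' @param response Trophic states (factor or codes 1--4).
#' @param n_trees Number of trees (default 5000).
#' @param seed Integer seed.
#' @return Object of class `importance_ranking`: a data.frame
#'   (`predictor`, `importance`) sorted descending with input-order
#'   tie-break, plus `n_trees` and `seed` attributes.
#' @export
rank_importance <- function(features, response, n_trees = 5000, seed = 1L) {
  stopifnot(n_trees >= 1)
  features <- as.data.frame(features)
  if (ncol(features) < 2) stop("need at least 2 candidate features", call. = FALSE)
  y <- as.numeric(.state_code(response))
  if (nrow(features) != length(y)) {
    stop("features and response must align", call. = FALSE)
  }
  const <- vapply(features, function(v) stats::var(as.numeric(v)) == 0, TRUE)
  if (any(const)) {
    warning("excluding zero-variance feature(s): ",
            paste(names(features)[const], collapse = ", "), call. = FALSE)
    features <- features[!const]
  }
  rf <- .with_seed(seed, .quiet_regression_forest(
    x = features, y = y, ntree = n_trees, importance = TRUE))
  imp <- randomForest::importance(rf)[, "%IncMSE"]
  ord <- order(-imp)  # stable: ties keep input order
  ranking <- data.frame(predictor = names(features)[ord],
                        importance = unname(imp[ord]),
                        stringsAsFactors = FALSE)
  structure(ranking, class = c("importance_ranking", "data.frame"),
            n_trees = n_trees, seed = seed)
}

# regression-mode forest on the 1..4 coded response; the "few unique
# values" warning is the deliberate design here, so it is muffled
.quiet_regression_forest <- function(...) {
  withCallingHandlers(
    randomForest::randomForest(...),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# chooses the smallest subset size beyond which no additional variable
# reduces the error curve by at least `threshold`
.choose_subset_size <- function(errors, threshold) {
  if (length(errors) == 1) return(1L)
  gains <- -diff(errors)                 # error reduction at each added variable
  useful <- which(gains >= threshold)
  if (length(useful) == 0) 1L else max(useful) + 1L
}

#' Select the minimal predictor subset
#'
#' Fits nested random forests on the top-m ranked predictors for
#' m = 1..`max_size`, records the out-of-bag mean squared error of each,
#' and selects the smallest m beyond which adding a variable no longer
#' reduces the error by at least `threshold` (default 0.1) — an elbow rule
#' on the error curve.
#'
#' @param features Candidate predictor table (as in [rank_importance()]).
#' @param response Trophic states.
#' @param ranking An `importance_ranking` for these features.
#' @param threshold Minimum error reduction that justifies another
#'   predictor (default 0.1).
#' @param max_size Largest subset size examined (default 15; silently
#'   capped at the number of ranked features).
#' @param n_trees Trees per nested forest (default 1000).
#' @param seed Integer seed.
#' @return Object of class `selection_curve`: data.frame (`size`, `mse`),
#'   with attributes `chosen_size`, `threshold`, `predictors` (the chosen
#'   subset, in ranking order).
#' @export
select_minimal_subset <- function(features, response, ranking,
                                  threshold = 0.1, max_size = 15,
                                  n_trees = 1000, seed = 1L) {
  stopifnot(inherits(ranking, "importance_ranking"), threshold > 0)
  features <- as.data.frame(features)
  y <- as.numeric(.state_code(response))
  M <- min(max_size, nrow(ranking))
  if (max_size > nrow(ranking)) {
    message("select_minimal_subset: max_size capped at ", M, " ranked features")
  }
  errors <- numeric(M)
  for (m in seq_len(M)) {
    cols <- ranking$predictor[seq_len(m)]
    rf <- .with_seed(seed + m, .quiet_regression_forest(
      x = features[cols], y = y, ntree = n_trees))
    errors[m] <- rf$mse[n_trees]
  }
  chosen <- .choose_subset_size(errors, threshold)
  structure(data.frame(size = seq_len(M), mse = errors),
            class = c("selection_curve", "data.frame"),
            chosen_size = chosen, threshold = threshold,
            predictors = ranking$predictor[seq_len(chosen)])
}

#' @export
print.selection_curve <- function(x, ...) {
  cat("Nested-forest selection curve (threshold ",
      attr(x, "threshold"), ")\n", sep = "")
  print.data.frame(x, ...)
  cat("Chosen subset size:", attr(x, "chosen_size"), "->",
      paste(attr(x, "predictors"), collapse = ", "), "\n")
  invisible(x)
}
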