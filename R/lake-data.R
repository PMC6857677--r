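# Lake tables, variable transformation, and the standardized design matrix.
#
# A "lakes" table is a plain data.frame with canonical columns
#   lake_id, secchi_m, tn_ugl, tp_ugl, elevation_m
# plus optional trophic_state and up to three single-variable reference
# classifications (ref_chla, ref_tn, ref_tp).  Secchi depth, total nitrogen
# and total phosphorus must be strictly positive because the model
# log-transforms them.

.REQUIRED_COLS <- c("lake_id", "secchi_m", "tn_ugl", "tp_ugl", "elevation_m")
.LABEL_COLS <- c("trophic_state", "ref_chla", "ref_tn", "ref_tp")
.PREDICTORS <- c("secchi", "nitrogen", "phosphorus", "elevation")

#' Default column-name map for lake tables
#'
#' Maps canonical column roles to the names used in a CSV file.  Override
#' entries to read files with different headers, e.g.
#' `lake_columns(secchi_m = "SECMEAN")`.
#'
#' @param ... Named overrides, one per canonical column.
#' @return Named character vector mapping canonical names to file columns.
#' @export
lake_columns <- function(...) {
  map <- c(lake_id = "lake_id", secchi_m = "secchi_m", tn_ugl = "tn_ugl",
           tp_ugl = "tp_ugl", elevation_m = "elevation_m",
           trophic_state = "trophic_state", ref_chla = "ref_chla",
           ref_tn = "ref_tn", ref_tp = "ref_tp")
  over <- c(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(map))
    if (length(unknown)) {
      stop("unknown column role(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    map[names(over)] <- over
  }
  map
}

#' Read a lake table from CSV
#'
#' Reads a per-lake table of water-quality measurements.  Rows with missing
#' required fields are dropped and the count is reported.  Secchi depth and
#' nutrient concentrations must be positive: under `strict = TRUE` a
#' non-positive value is an error (the model takes their logarithm); under
#' `strict = FALSE` such rows are dropped with the missing rows.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Column-name map from [lake_columns()].
#' @param strict Logical; error on non-positive Secchi/TN/TP (default) rather
#'   than dropping the rows.
#' @return A data.frame with canonical columns; `trophic_state` and reference
#'   labels, when present, are ordered factors.
#' @export
read_lakes <- function(path, dialect = lake_columns(), strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- .REQUIRED_COLS[!(dialect[.REQUIRED_COLS] %in% names(raw))]
  if (length(missing_cols)) {
    stop("missing required column '", missing_cols[1L], "' (expected header '",
         dialect[missing_cols[1L]], "')", call. = FALSE)
  }
  out <- data.frame(lake_id = as.character(raw[[dialect["lake_id"]]]),
                    stringsAsFactors = FALSE)
  for (col in c("secchi_m", "tn_ugl", "tp_ugl", "elevation_m")) {
    v <- raw[[dialect[col]]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(num))
      if (length(bad)) {
        stop("non-numeric value '", v[bad[1L]], "' in column '", dialect[col],
             "' at data row ", bad[1L], call. = FALSE)
      }
      v <- num
    }
    out[[col]] <- v
  }
  for (col in .LABEL_COLS) {
    if (dialect[col] %in% names(raw)) {
      v <- raw[[dialect[col]]]
      v[v %in% c("", "NA")] <- NA
      out[[col]] <- as_trophic_state(v)
    }
  }
  complete <- stats::complete.cases(out[.REQUIRED_COLS])
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message("read_lakes: dropped ", n_drop, " row(s) with missing required fields")
    out <- out[complete, , drop = FALSE]
  }
  nonpos <- out$secchi_m <= 0 | out$tn_ugl <= 0 | out$tp_ugl <= 0
  if (any(nonpos)) {
    if (strict) {
      stop("non-positive Secchi/TN/TP in ", sum(nonpos),
           " row(s): outside the log transform domain (first lake_id: ",
           out$lake_id[which(nonpos)[1L]], ")", call. = FALSE)
    }
    message("read_lakes: dropped ", sum(nonpos),
            " row(s) with non-positive Secchi/TN/TP")
    out <- out[!nonpos, , drop = FALSE]
  }
  if (anyDuplicated(out$lake_id)) {
    warning("duplicate lake_id values present", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write a lake table to CSV
#'
#' @param lakes Lake data.frame (canonical columns).
#' @param path Output path.
#' @param dialect Column-name map from [lake_columns()].
#' @return `path`, invisibly.
#' @export
write_lakes <- function(lakes, path, dialect = lake_columns()) {
  out <- lakes
  keep <- intersect(names(dialect), names(out))
  out <- out[keep]
  names(out) <- dialect[keep]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.check_positive <- function(lakes) {
  for (col in c("secchi_m", "tn_ugl", "tp_ugl")) {
    if (any(lakes[[col]] <= 0)) {
      stop("column ", col, " must be strictly positive (log transform domain)",
           call. = FALSE)
    }
  }
  invisible(lakes)
}

# raw lakes -> matrix of transformed (but not yet standardized) predictors,
# fixed column order (secchi, nitrogen, phosphorus, elevation)
.transformed_matrix <- function(lakes) {
  .check_positive(lakes)
  m <- cbind(secchi = log(lakes$secchi_m),
             nitrogen = log(lakes$tn_ugl),
             phosphorus = log(lakes$tp_ugl),
             elevation = lakes$elevation_m)
  rownames(m) <- lakes$lake_id
  m
}

#' Fit predictor standardization on a training set
#'
#' Natural-log transforms Secchi depth, total nitrogen and total phosphorus
#' (environmental concentrations are approximately log-normal), leaves
#' elevation on its raw scale, then records each predictor's mean and
#' standard deviation (n−1 denominator).  The resulting spec centers and
#' scales new data so model coefficients live on a common standardized scale.
#'
#' @param lakes Lake data.frame with at least 2 rows.
#' @return An object of class `standardization_spec` with elements `center`,
#'   `scale` (named numeric, order secchi/nitrogen/phosphorus/elevation) and
#'   `log_transformed` (logical flags).
#' @export
fit_standardization <- function(lakes) {
  if (nrow(lakes) < 2) {
    stop("need at least 2 lakes to fit standardization", call. = FALSE)
  }
  m <- .transformed_matrix(lakes)
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  if (any(scale == 0)) {
    stop("degenerate data: predictor '",
         names(scale)[which(scale == 0)[1L]],
         "' is constant across lakes (zero variance)", call. = FALSE)
  }
  structure(list(center = center, scale = scale,
                 log_transformed = c(secchi = TRUE, nitrogen = TRUE,
                                     phosphorus = TRUE, elevation = FALSE)),
            class = "standardization_spec")
}

#' Build the standardized design matrix
#'
#' Applies a fitted [fit_standardization()] spec: log-transform where the
#' spec says so, subtract the training center, divide by the training scale.
#' Prediction on new lakes must reuse the training spec; never re-fit it on
#' evaluation data.
#'
#' @param lakes Lake data.frame.
#' @param spec A `standardization_spec`.
#' @return Numeric matrix, n rows by 4 columns
#'   (secchi, nitrogen, phosphorus, elevation), rownames = lake ids.
#' @export
apply_standardization <- function(lakes, spec) {
  stopifnot(inherits(spec, "standardization_spec"))
  m <- .transformed_matrix(lakes)
  sweep(sweep(m, 2, spec$center, "-"), 2, spec$scale, "/")
}

#' Invert standardization back to raw measurements
#'
#' Reverses [apply_standardization()]: multiplies by the scale, adds the
#' center, and exponentiates log-transformed predictors.  Used mainly to
#' check the transform round-trip and to materialize simulated designs as
#' raw measurement tables.
#'
#' @param X Standardized design matrix (4 columns).
#' @param spec The `standardization_spec` used to build `X`.
#' @return Lake data.frame with columns lake_id, secchi_m, tn_ugl, tp_ugl,
#'   elevation_m.
#' @export
destandardize <- function(X, spec) {
  stopifnot(inherits(spec, "standardization_spec"))
  m <- sweep(sweep(X, 2, spec$scale, "*"), 2, spec$center, "+")
  m[, spec$log_transformed] <- exp(m[, spec$log_transformed])
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("lake_%05d", seq_len(nrow(X)))
  data.frame(lake_id = ids, secchi_m = m[, "secchi"], tn_ugl = m[, "nitrogen"],
             tp_ugl = m[, "phosphorus"], elevation_m = m[, "elevation"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.standardization_spec <- function(x, ...) {
  cat("Predictor standardization (fitted on training data)\n")
  tab <- data.frame(log = ifelse(x$log_transformed, "ln", "-"),
                    center = x$center, scale = x$scale)
  print(tab, ...)
  invisible(x)
}

#' Keep only consensus-classified lakes
#'
#' The three classical single-variable trophic classifications (chlorophyll
#' a, total nitrogen, total phosphorus) often disagree; evaluation data is
#' restricted to lakes on which all available reference schemes agree.
#' Lakes with fewer than two reference labels are dropped; lakes whose
#' labels all coincide are kept with `trophic_state` set to the consensus.
#'
#' @param lakes Lake data.frame with reference label columns
#'   (`ref_chla`, `ref_tn`, `ref_tp`).
#' @return The consensus subset, with `trophic_state` filled in.
#' @export
consensus_filter <- function(lakes) {
  refs <- intersect(c("ref_chla", "ref_tn", "ref_tp"), names(lakes))
  if (length(refs) == 0) {
    stop("no reference label columns present", call. = FALSE)
  }
  lab <- sapply(lakes[refs], .state_code)
  if (!is.matrix(lab)) lab <- matrix(lab, nrow = nrow(lakes))
  n_lab <- rowSums(!is.na(lab))
  if (all(n_lab == 0)) {
    stop("no lake carries any reference label", call. = FALSE)
  }
  rng <- t(apply(lab, 1, range, na.rm = TRUE))
  keep <- n_lab >= 2 & rng[, 1] == rng[, 2]
  out <- lakes[keep, , drop = FALSE]
  out$trophic_state <- as_trophic_state(rng[keep, 1])
  rownames(out) <- NULL
  out
}

#' Split lakes into training and evaluation sets
#'
#' Simple hold-out partition; the evaluation set holds
#' `round(n * eval_fraction)` lakes (at least one).  Deterministic for a
#' fixed seed.
#'
#' @param lakes Lake data.frame with at least 2 rows.
#' @param eval_fraction Proportion held out for evaluation, default 0.1
#'   (a 90/10 split).
#' @param seed Integer seed.
#' @return List with elements `train` and `eval`, disjoint and exhaustive.
#' @export
holdout_split <- function(lakes, eval_fraction = 0.1, seed = 1L) {
  n <- nrow(lakes)
  if (n < 2) stop("need at least 2 lakes to split", call. = FALSE)
  if (!(eval_fraction > 0 && eval_fraction < 1)) {
    stop("eval_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_eval <- max(1L, as.integer(round(n * eval_fraction)))
  idx <- .with_seed(seed, sample.int(n, n_eval))
  list(train = lakes[-idx, , drop = FALSE],
       eval = lakes[idx, , drop = FALSE])
}

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
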