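# Proportional-odds model math: the continuous trophic state index
# eta = X %*% A, exceedance and class probabilities, interval and
# maximum-probability classifiers, and a numerically stable log-likelihood.
#
# Latent formulation: observed class k  iff  z in [c_{k-1}, c_k) with
# z ~ logistic(eta, 1); equivalently logit Pr(state > k) = eta - c_k.

#' Construct proportional-odds model parameters
#'
#' The model has one slope per standardized predictor and three ordered
#' cutpoints on the index scale separating the four trophic states.  The
#' latent logistic noise scale is fixed at 1: with a free location (the
#' cutpoints) and free slopes a free scale would not be identifiable.
#'
#' @param coefficients Named numeric length 4, order
#'   (secchi, nitrogen, phosphorus, elevation).
#' @param cutpoints Numeric length 3, strictly increasing: the
#'   oligo/meso, meso/eu and eu/hyper thresholds.
#' @param latent_scale Positive scale of the latent logistic noise; fixed at
#'   1 in this parameterization and recorded for metadata only.
#' @return Object of class `polr_params`.
#' @export
polr_params <- function(coefficients, cutpoints, latent_scale = 1) {
  nm <- names(coefficients)
  if (is.null(nm)) nm <- .PREDICTORS[seq_along(coefficients)]
  coefficients <- stats::setNames(as.numeric(coefficients), nm)
  if (length(coefficients) != 4) {
    stop("exactly 4 slope coefficients required", call. = FALSE)
  }
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) != 3) stop("exactly 3 cutpoints required", call. = FALSE)
  if (any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(latent_scale) || latent_scale <= 0) {
    stop("latent_scale must be positive", call. = FALSE)
  }
  names(cutpoints) <- c("oligo|meso", "meso|eu", "eu|hyper")
  structure(list(coefficients = coefficients, cutpoints = cutpoints,
                 latent_scale = latent_scale),
            class = "polr_params")
}

#' National-scale fitted trophic state model
#'
#' The proportional-odds coefficients and cutpoints fitted to the
#' consensus-classified lakes of the EPA 2007 National Lakes Assessment:
#' TSI = −1.69·Secchi + 0.69·N + 0.55·P − 0.56·Elevation on the
#' standardized scale, with cutpoints (−3.36, −0.18, 2.62).  Useful as a
#' reference parameterization and as the default generator for simulations.
#'
#' @return A `polr_params` object.
#' @export
#' @examples
#' nla_polr_params()
nla_polr_params <- function() {
  polr_params(coefficients = c(secchi = -1.69, nitrogen = 0.69,
                               phosphorus = 0.55, elevation = -0.56),
              cutpoints = c(-3.36, -0.18, 2.62))
}

#' @export
print.polr_params <- function(x, ...) {
  cat("Proportional-odds trophic state model\n")
  cat("Coefficients (standardized scale):\n")
  print(round(x$coefficients, 4))
  cat("Cutpoints:\n")
  print(round(x$cutpoints, 4))
  invisible(x)
}

#' Continuous trophic state index
#'
#' The linear predictor eta = X A: a single continuous number locating each
#' lake along the trophic continuum.  Larger values mean more eutrophic.
#'
#' @param X Standardized design matrix (or a single row as a length-4
#'   vector), column order (secchi, nitrogen, phosphorus, elevation).
#' @param params `polr_params`.
#' @return Numeric vector of index values, one per row.
#' @export
trophic_index <- function(X, params) {
  stopifnot(inherits(params, "polr_params"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != 4) {
    stop("design matrix must have 4 columns, got ", ncol(X), call. = FALSE)
  }
  if (!all(is.finite(X))) stop("design matrix has non-finite entries", call. = FALSE)
  drop(X %*% params$coefficients)
}

#' Probability of exceeding a trophic state
#'
#' `Pr(state > k) = logistic(eta - c_k)` for k = 1, 2, 3; by convention
#' `Pr(state > 0) = 1` and `Pr(state > 4) = 0`.
#'
#' @param eta Trophic index value(s).
#' @param k State level to exceed (0--4, usually 1--3).
#' @param params `polr_params`.
#' @return Probability vector, same length as `eta`.
#' @export
exceedance_probability <- function(eta, k, params) {
  stopifnot(inherits(params, "polr_params"), length(k) == 1)
  if (!(k %in% 0:4)) stop("k must be an integer in 0..4", call. = FALSE)
  if (k == 0) return(rep(1, length(eta)))
  if (k == 4) return(rep(0, length(eta)))
  stats::plogis(eta - params$cutpoints[[k]])
}

# n x 4 matrix of log class probabilities, numerically stable.
# log p_1 = log F(c1 - eta); log p_4 = log F(eta - c3);
# middle classes via log-diff-exp of log CDFs so that F(a) - F(b) never
# suffers catastrophic cancellation for |eta| up to ~30.
.log_class_prob <- function(eta, cutpoints) {
  cutpoints <- unname(cutpoints)
  eta <- unname(eta)
  c1 <- cutpoints[1]; c2 <- cutpoints[2]; c3 <- cutpoints[3]
  logdiff <- function(lo, hi) { # log(F(hi - eta) - F(lo - eta))
    la <- stats::plogis(hi - eta, log.p = TRUE)
    lb <- stats::plogis(lo - eta, log.p = TRUE)
    d <- lb - la                       # <= 0
    # log(1 - e^d): use expm1 near 0 and log1p in the far tail (log1mexp)
    small <- d > -log(2)
    l1me <- numeric(length(d))
    l1me[small] <- log(-expm1(d[small]))
    l1me[!small] <- log1p(-exp(d[!small]))
    out <- la + l1me
    out[d >= 0] <- -Inf                # probability 0 at working precision
    out
  }
  m <- cbind(stats::plogis(c1 - eta, log.p = TRUE),
             logdiff(c1, c2),
             logdiff(c2, c3),
             stats::plogis(eta - c3, log.p = TRUE))
  colnames(m) <- trophic_levels()
  m
}

#' Class probabilities for the four trophic states
#'
#' For each index value the probability of each state is the logistic
#' probability mass between adjacent cutpoints:
#' `p_k = Pr(state > k-1) - Pr(state > k)`.  Rows always sum to 1.
#'
#' @param eta Trophic index value(s).
#' @param params `polr_params`.
#' @return Numeric matrix, one row per index value, columns named by state.
#' @export
class_probabilities <- function(eta, params) {
  stopifnot(inherits(params, "polr_params"))
  exp(.log_class_prob(eta, params$cutpoints))
}

#' Classify by latent interval
#'
#' The published classification rule: a lake is oligotrophic when its index
#' (or latent draw) falls below the first cutpoint, hypereutrophic above the
#' last, and so on.  Boundary values are assigned upward (half-open
#' intervals, top class closed below).
#'
#' @param z Index or latent values.
#' @param params `polr_params`.
#' @return Ordered factor of trophic states.
#' @export
classify_interval <- function(z, params) {
  stopifnot(inherits(params, "polr_params"))
  if (any(!is.finite(z))) stop("non-finite index value", call. = FALSE)
  as_trophic_state(findInterval(z, params$cutpoints) + 1L)
}

#' Classify by maximum probability
#'
#' Assigns the state with the highest class probability; ties break toward
#' the lower (less eutrophic) state.  Near a cutpoint this can differ from
#' [classify_interval()] by a narrow band, because the modal class switches
#' where adjacent interval masses are equal, not exactly at the cutpoint.
#'
#' @param probs Matrix (or length-4 vector) of class probabilities.
#' @return Ordered factor of trophic states.
#' @export
classify_map <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != 4) stop("need 4 class probabilities", call. = FALSE)
  if (any(probs < -1e-12) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("rows must be probability vectors summing to 1", call. = FALSE)
  }
  as_trophic_state(max.col(probs, ties.method = "first"))
}

#' Log-likelihood of the proportional-odds model
#'
#' Sum over lakes of the log probability of the observed state, computed on
#' the log scale with stable CDF-difference identities.  Returns `-Inf`
#' (not an error) when any observation has zero probability at working
#' precision.
#'
#' @param params `polr_params`.
#' @param X Standardized design matrix, rows aligned with `y`.
#' @param y Observed trophic states (factor or codes 1--4).
#' @return The log-likelihood (a single number).
#' @export
polr_log_likelihood <- function(params, X, y) {
  stopifnot(inherits(params, "polr_params"))
  y <- .state_code(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 4)
  if (nrow(X) != length(y)) stop("rows of X must align with y", call. = FALSE)
  eta <- trophic_index(X, params)
  lp <- .log_class_prob(eta, params$cutpoints)
  sum(lp[cbind(seq_along(y), y)])
}

# gradient of the total log-likelihood w.r.t. (A, c); returns length-7
# named vector.  Shared by the fitter (through the cutpoint
# reparameterization) and by the standard-error computation.
.polr_loglik_grad <- function(coefficients, cutpoints, X, y_int, eta = NULL) {
  if (is.null(eta)) eta <- drop(X %*% coefficients)
  cut_ext <- c(-Inf, cutpoints, Inf)
  u <- cut_ext[y_int + 1L] - eta   # upper bound of the observed interval
  l <- cut_ext[y_int] - eta        # lower bound
  lp <- .log_class_prob(eta, cutpoints)[cbind(seq_along(y_int), y_int)]
  ratio <- function(b) { # f(b) / p_i, 0 where b infinite
    lf <- stats::dlogis(b, log = TRUE)
    r <- exp(lf - lp)
    r[!is.finite(b)] <- 0
    r
  }
  r_u <- ratio(u); r_l <- ratio(l)
  dl_deta <- r_l - r_u
  gA <- drop(crossprod(X, dl_deta))
  gc <- numeric(3)
  for (m in 1:3) {
    gc[m] <- sum(r_u[y_int == m]) - sum(r_l[y_int == m + 1L])
  }
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("b", seq_len(ncol(X)))
  stats::setNames(c(gA, gc), c(cn, c("oligo|meso", "meso|eu", "eu|hyper")))
}
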