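# Maximum-likelihood and Bayesian estimation of the proportional-odds
# model.  The ordered-cutpoint constraint is handled by the unconstrained
# reparameterization c = (t1, t1 + e^{t2}, t1 + e^{t2} + e^{t3}); the
# optimizer works on theta = (A, t1, t2, t3) with an analytic gradient,
# then a Newton polish drives the gradient norm to the requested tolerance.

.theta_to_cut <- function(tc) cumsum(c(tc[1], exp(tc[2]), exp(tc[3])))
.cut_to_theta <- function(cut) c(cut[1], log(diff(cut)))

# negative MEAN log-likelihood and its gradient in theta space
.nll_theta <- function(theta, X, y_int) {
  A <- theta[1:4]
  cut <- .theta_to_cut(theta[5:7])
  eta <- drop(X %*% A)
  lp <- .log_class_prob(eta, cut)
  -mean(lp[cbind(seq_along(y_int), y_int)])
}

.nll_grad_theta <- function(theta, X, y_int) {
  A <- theta[1:4]
  tc <- theta[5:7]
  cut <- .theta_to_cut(tc)
  g <- .polr_loglik_grad(A, stats::setNames(cut, c("oligo|meso", "meso|eu", "eu|hyper")),
                         X, y_int)
  gc <- g[5:7]
  gtheta <- c(g[1:4],
              sum(gc),
              (gc[2] + gc[3]) * exp(tc[2]),
              gc[3] * exp(tc[3]))
  -gtheta / nrow(X)
}

# finite-difference Hessian of the negative mean log-likelihood (theta
# space), built from the analytic gradient
.nll_hess_theta <- function(theta, X, y_int, h = 1e-5) {
  p <- length(theta)
  H <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    hj <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    H[, j] <- (.nll_grad_theta(tp, X, y_int) - .nll_grad_theta(tm, X, y_int)) / (2 * hj)
  }
  (H + t(H)) / 2
}

.validate_fit_inputs <- function(X, y) {
  y_int <- .state_code(y)
  if (is.null(dim(X))) X <- matrix(X, ncol = 4)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- .PREDICTORS[seq_len(ncol(X))]
  if (nrow(X) != length(y_int)) stop("rows of X must align with y", call. = FALSE)
  if (anyNA(y_int) || anyNA(X)) stop("missing values in fit inputs", call. = FALSE)
  if (nrow(X) < 20) {
    stop("insufficient data: need at least 20 labeled lakes", call. = FALSE)
  }
  absent <- setdiff(1:4, unique(y_int))
  if (length(absent)) {
    stop("non-identifiable: class '", trophic_levels()[absent[1L]],
         "' absent from the training labels", call. = FALSE)
  }
  const <- apply(X, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    stop("constant design column: ", colnames(X)[which(const)[1L]],
         call. = FALSE)
  }
  list(X = X, y_int = y_int)
}

#' Fit the proportional-odds model by maximum likelihood
#'
#' Estimates the four slope coefficients and three ordered cutpoints
#' simultaneously by maximizing the log-likelihood, using quasi-Newton
#' (BFGS) steps with an analytic gradient followed by Newton polishing.
#' Cutpoint ordering is enforced through a log-increment
#' reparameterization.  Standard errors come from the inverse observed
#' information (the Hessian of the negative log-likelihood at the optimum,
#' on the natural coefficient/cutpoint scale).
#'
#' @param X Standardized design matrix (4 columns) from
#'   [apply_standardization()] or a simulated design.
#' @param y Observed trophic states, aligned with the rows of `X`.
#' @param tol Convergence tolerance: largest absolute component of the
#'   per-observation (mean) log-likelihood gradient at the reported optimum.
#' @param init Optional `polr_params` starting point; the default starts at
#'   zero coefficients with cutpoints at the logits of the cumulative class
#'   frequencies.
#' @param max_iter Maximum BFGS iterations.
#' @return Object of class `polr_fit`: fields `params`, `se`, `vcov`,
#'   `log_likelihood`, `n`, `converged`, `method = "mle"`.
#' @export
fit_polr_mle <- function(X, y, tol = 1e-8, init = NULL, max_iter = 500) {
  v <- .validate_fit_inputs(X, y)
  X <- v$X; y_int <- v$y_int
  n <- nrow(X)
  if (is.null(init)) {
    cum <- cumsum(tabulate(y_int, 4))[1:3] / n
    theta0 <- c(rep(0, 4), .cut_to_theta(stats::qlogis(cum)))
  } else {
    stopifnot(inherits(init, "polr_params"))
    theta0 <- c(init$coefficients, .cut_to_theta(init$cutpoints))
  }
  opt <- stats::optim(theta0, fn = .nll_theta, gr = .nll_grad_theta,
                      X = X, y_int = y_int, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  theta <- opt$par
  # Newton polish: quadratic convergence pushes the mean-gradient norm
  # below tol, which BFGS alone rarely achieves
  f_cur <- .nll_theta(theta, X, y_int)
  for (it in 1:40) {
    g <- .nll_grad_theta(theta, X, y_int)
    if (max(abs(g)) < tol) break
    H <- .nll_hess_theta(theta, X, y_int)
    step <- tryCatch(solve(H, g), error = function(e) g)
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      f_new <- .nll_theta(cand, X, y_int)
      if (is.finite(f_new) && f_new <= f_cur + 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- theta; f_new <- f_cur; break }
    }
    if (max(abs(cand - theta)) == 0) break
    theta <- cand; f_cur <- f_new
  }
  g_final <- .nll_grad_theta(theta, X, y_int)
  converged <- is.finite(f_cur) && max(abs(g_final)) < tol
  A <- stats::setNames(theta[1:4], colnames(X))
  cut <- .theta_to_cut(theta[5:7])
  separation <- any(abs(A) > 25) || any(abs(cut) > 50)
  if (separation) {
    warning("possible perfect separation: unbounded likelihood suspected ",
            "(|coefficient| > 25); estimates unreliable", call. = FALSE)
    converged <- FALSE
  }
  params <- polr_params(A, cut)
  ll <- polr_log_likelihood(params, X, y_int)
  # observed information on the natural (A, c) scale
  se <- rep(NA_real_, 7)
  vcov <- NULL
  grad_nat <- function(par) {
    -.polr_loglik_grad(par[1:4], stats::setNames(par[5:7], names(params$cutpoints)),
                       X, y_int)
  }
  par_nat <- c(A, cut)
  Hn <- matrix(NA_real_, 7, 7)
  for (j in 1:7) {
    hj <- 1e-5 * max(1, abs(par_nat[j]))
    pp <- par_nat; pp[j] <- pp[j] + hj
    pm <- par_nat; pm[j] <- pm[j] - hj
    Hn[, j] <- (grad_nat(pp) - grad_nat(pm)) / (2 * hj)
  }
  Hn <- (Hn + t(Hn)) / 2
  vcov <- tryCatch(solve(Hn), error = function(e) NULL)
  if (!is.null(vcov) && all(diag(vcov) > 0)) {
    se <- sqrt(diag(vcov))
  }
  nm <- c(names(A), names(params$cutpoints))
  names(se) <- nm
  if (!is.null(vcov)) dimnames(vcov) <- list(nm, nm)
  structure(list(params = params, se = se, vcov = vcov,
                 log_likelihood = ll, n = n, converged = converged,
                 method = "mle", iterations = opt$counts[["function"]] + it,
                 gradient_norm = max(abs(g_final))),
            class = "polr_fit")
}

#' @export
print.polr_fit <- function(x, ...) {
  cat("Proportional-odds trophic state fit (", x$method, ")\n", sep = "")
  est <- c(x$params$coefficients, x$params$cutpoints)
  tab <- data.frame(estimate = est, std_error = x$se)
  print(round(tab, 4))
  cat("n =", x$n, " log-likelihood =", format(x$log_likelihood),
      " converged:", x$converged, "\n")
  if (!is.null(x$rhat)) {
    cat("max split R-hat:", round(max(x$rhat), 4), "\n")
  }
  invisible(x)
}

# split R-hat (potential scale reduction) for a draws matrix organized as
# chains stacked in order; each chain split in half
.split_rhat <- function(draws, chains) {
  n <- nrow(draws) / chains
  half <- floor(n / 2)
  seqs <- list()
  for (c in seq_len(chains)) {
    block <- draws[((c - 1) * n + 1):(c * n), , drop = FALSE]
    seqs[[2 * c - 1]] <- block[seq_len(half), , drop = FALSE]
    seqs[[2 * c]] <- block[(half + 1):(2 * half), , drop = FALSE]
  }
  vapply(seq_len(ncol(draws)), function(j) {
    means <- vapply(seqs, function(s) mean(s[, j]), 0)
    vars <- vapply(seqs, function(s) stats::var(s[, j]), 0)
    B <- half * stats::var(means)
    W <- mean(vars)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, 0)
}

#' Fit the proportional-odds model by posterior sampling
#'
#' Random-walk Metropolis sampling of the coefficients and ordered
#' cutpoints under weakly-informative priors: independent Cauchy(0,
#' `prior_scale`) on the standardized coefficients and flat priors on the
#' ordered cutpoints.  The proposal covariance is the MLE curvature scaled
#' by 2.4^2/d.  Chains start from jittered MLE estimates; reported
#' estimates are posterior means with posterior standard deviations, and a
#' split R-hat is computed per parameter (a value above 1.1 raises a
#' convergence warning recorded in the result).
#'
#' @param X Standardized design matrix (4 columns).
#' @param y Observed trophic states.
#' @param prior_scale Scale of the heavy-tailed coefficient prior
#'   (default 2.5, appropriate for standardized predictors).
#' @param chains Number of independent chains (at least 2).
#' @param draws Retained draws per chain after warm-up.
#' @param warmup Discarded initial iterations per chain.
#' @param seed Integer seed; fixed seed gives identical posterior summaries.
#' @return `polr_fit` with `method = "bayes"`, plus `posterior_draws`
#'   (draws x 7 matrix), `rhat`, and `accept_rate`.
#' @export
fit_polr_bayes <- function(X, y, prior_scale = 2.5, chains = 4,
                           draws = 2000, warmup = 1000, seed = 1L) {
  if (chains < 2) stop("need at least 2 chains", call. = FALSE)
  v <- .validate_fit_inputs(X, y)
  X <- v$X; y_int <- v$y_int
  n <- nrow(X)
  mle <- fit_polr_mle(X, y_int)
  theta_hat <- c(mle$params$coefficients, .cut_to_theta(mle$params$cutpoints))
  H <- .nll_hess_theta(theta_hat, X, y_int)
  Sigma <- tryCatch(solve(H * n), error = function(e) diag(7) * 0.01)
  if (any(!is.finite(Sigma)) || any(diag(Sigma) <= 0)) Sigma <- diag(7) * 0.01
  prop_chol <- tryCatch(chol(Sigma * 2.4^2 / 7),
                        error = function(e) diag(sqrt(diag(Sigma)) * 2.4 / sqrt(7)))
  # log posterior in theta space: likelihood + Cauchy prior on A +
  # flat-on-ordered-cutpoints prior (Jacobian t2 + t3)
  log_post <- function(theta) {
    ll <- -n * .nll_theta(theta, X, y_int)
    if (!is.finite(ll)) return(-Inf)
    ll + sum(stats::dcauchy(theta[1:4], 0, prior_scale, log = TRUE)) +
      theta[6] + theta[7]
  }
  total <- warmup + draws
  all_draws <- matrix(NA_real_, chains * draws, 7)
  accept <- 0
  .with_seed(seed, {
    for (ch in seq_len(chains)) {
      theta <- theta_hat + drop(stats::rnorm(7) %*% prop_chol)
      lp <- log_post(theta)
      for (i in seq_len(total)) {
        cand <- theta + drop(stats::rnorm(7) %*% prop_chol)
        lp_cand <- log_post(cand)
        if (log(stats::runif(1)) < lp_cand - lp) {
          theta <- cand; lp <- lp_cand
          if (i > warmup) accept <- accept + 1
        }
        if (i > warmup) {
          all_draws[(ch - 1) * draws + (i - warmup), ] <-
            c(theta[1:4], .theta_to_cut(theta[5:7]))
        }
      }
    }
  })
  nm <- c(colnames(X), names(mle$params$cutpoints))
  colnames(all_draws) <- nm
  post_mean <- colMeans(all_draws)
  post_sd <- apply(all_draws, 2, stats::sd)
  rhat <- stats::setNames(.split_rhat(all_draws, chains), nm)
  warn <- character(0)
  if (any(rhat > 1.1)) {
    warn <- paste0("split R-hat > 1.1 for: ",
                   paste(nm[rhat > 1.1], collapse = ", "))
    warning(warn, call. = FALSE)
  }
  params <- polr_params(post_mean[1:4], post_mean[5:7])
  structure(list(params = params, se = post_sd, vcov = stats::cov(all_draws),
                 log_likelihood = polr_log_likelihood(params, X, y_int),
                 n = n, converged = all(rhat <= 1.1), method = "bayes",
                 seed = seed, posterior_draws = all_draws, rhat = rhat,
                 accept_rate = accept / (chains * draws),
                 warnings = warn),
            class = "polr_fit")
}

#' Assemble a trophic state model from parameters and a standardization
#'
#' Bundles existing `polr_params` (for example the published national
#' coefficients from [nla_polr_params()]) with a standardization spec so
#' the pair can be used with [predict_lakes()] and [evaluate_holdout()]
#' without refitting.
#'
#' @param params `polr_params`.
#' @param standardization Optional `standardization_spec`.
#' @param se Optional named standard errors.
#' @param meta Optional metadata list.
#' @return Object of class `trophic_model`.
#' @export
trophic_model <- function(params, standardization = NULL, se = NULL,
                          meta = list()) {
  stopifnot(inherits(params, "polr_params"))
  if (!is.null(standardization)) {
    stopifnot(inherits(standardization, "standardization_spec"))
  }
  structure(list(params = params, standardization = standardization,
                 se = se, fit = NULL, meta = meta),
            class = "trophic_model")
}

#' Fit the full trophic state model from a labeled lake table
#'
#' Pipeline convenience: fits the standardization on the supplied lakes,
#' builds the design matrix, and estimates the proportional-odds parameters
#' (maximum likelihood by default, or posterior sampling).  The returned
#' bundle carries everything needed to predict new lakes and can be
#' serialized with [write_polr_model()].
#'
#' @param lakes Lake data.frame with a `trophic_state` column.
#' @param method `"mle"` or `"bayes"`.
#' @param seed Seed recorded in metadata and used by the Bayesian sampler.
#' @param ... Passed on to [fit_polr_mle()] or [fit_polr_bayes()].
#' @return Object of class `trophic_model` with fields `params`,
#'   `standardization`, `se`, `fit`, `meta`.
#' @export
fit_trophic_model <- function(lakes, method = c("mle", "bayes"), seed = 1L, ...) {
  method <- match.arg(method)
  if (!("trophic_state" %in% names(lakes)) || all(is.na(lakes$trophic_state))) {
    stop("lakes must carry a trophic_state column to fit", call. = FALSE)
  }
  keep <- !is.na(lakes$trophic_state)
  lakes <- lakes[keep, , drop = FALSE]
  spec <- fit_standardization(lakes)
  X <- apply_standardization(lakes, spec)
  fit <- switch(method,
                mle = fit_polr_mle(X, lakes$trophic_state, ...),
                bayes = fit_polr_bayes(X, lakes$trophic_state, seed = seed, ...))
  structure(list(params = fit$params, standardization = spec,
                 se = fit$se, fit = fit,
                 meta = list(method = method, seed = seed, n = fit$n,
                             log_likelihood = fit$log_likelihood,
                             converged = fit$converged,
                             training_ids = lakes$lake_id)),
            class = "trophic_model")
}

#' Predict trophic state for new lakes
#'
#' Standardizes with the model's training spec, computes the continuous
#' trophic state index, the four class probabilities, and the interval
#' classification.
#'
#' @param model A `trophic_model`.
#' @param lakes Lake data.frame of new observations.
#' @return data.frame with columns `lake_id`, `tsi`, the four class
#'   probabilities (`p_oligotrophic` .. `p_hypereutrophic`) and
#'   `predicted_class`.
#' @export
predict_lakes <- function(model, lakes) {
  stopifnot(inherits(model, "trophic_model"))
  if (is.null(model$standardization)) {
    stop("model carries no standardization spec", call. = FALSE)
  }
  X <- apply_standardization(lakes, model$standardization)
  eta <- trophic_index(X, model$params)
  probs <- class_probabilities(eta, model$params)
  colnames(probs) <- paste0("p_", trophic_levels())
  data.frame(lake_id = lakes$lake_id, tsi = eta, probs,
             predicted_class = classify_interval(eta, model$params),
             stringsAsFactors = FALSE, row.names = NULL)
}
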