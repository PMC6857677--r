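# Generative simulator for National Lakes Assessment style data from the
# latent-logistic ordinal model, so every pipeline stage is testable
# without external downloads.

#' Default raw-scale predictor distributions for simulation
#'
#' NLA-like marginals: Secchi depth, total nitrogen and total phosphorus
#' are log-normal (median 2 m, 600 ug/L and 30 ug/L respectively, log-SD 1
#' — environmental concentrations are canonically log-normal), elevation
#' approximately normal (mean 400 m, SD 500 m; values at or below sea
#' level are legitimate).
#'
#' @return Named list of distribution parameters, one entry per predictor.
#' @export
raw_predictor_defaults <- function() {
  list(secchi = c(meanlog = log(2), sdlog = 1),
       nitrogen = c(meanlog = log(600), sdlog = 1),
       phosphorus = c(meanlog = log(30), sdlog = 1),
       elevation = c(mean = 400, sd = 500))
}

#' Simulate lakes from the latent trophic state model
#'
#' Draws predictors, computes the continuous index eta = X A, adds
#' standard-logistic latent noise z = eta + logistic(0, 1) (via inverse-CDF
#' sampling of uniform deviates for platform-stable reproducibility), and
#' labels each lake by the interval rule on z.
#'
#' Two predictor modes:
#' \describe{
#'   \item{standardized}{4 iid standard-normal predictors; the design is
#'     used as-is and the generating coefficients live on this scale.}
#'   \item{raw}{log-normal Secchi/TN/TP and normal elevation drawn from
#'     `raw_params`; the pipeline's own standardization then produces the
#'     design, exercising the full read-transform-fit path.}
#' }
#'
#' @param n Number of lakes (0 gives an empty dataset).
#' @param params Generating `polr_params` (default [nla_polr_params()]).
#' @param mode `"standardized"` or `"raw"`.
#' @param raw_params Raw-mode distribution parameters
#'   (default [raw_predictor_defaults()]).
#' @param seed Integer seed; fixed seed reproduces the dataset exactly.
#' @return Object of class `synthetic_lakes`: list with `lakes` (data.frame
#'   with `trophic_state` set; raw measurement columns in raw mode),
#'   `design` (the standardized matrix actually used), `latent`
#'   (data.frame of per-lake `eta` and `z`), and `truth` (the generating
#'   configuration).
#' @export
simulate_lakes <- function(n, params = nla_polr_params(),
                           mode = c("standardized", "raw"),
                           raw_params = raw_predictor_defaults(),
                           seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "polr_params"), n >= 0)
  truth <- list(n = n, params = params, mode = mode,
                raw_params = if (mode == "raw") raw_params, seed = seed)
  ids <- if (n > 0) sprintf("lake_%06d", seq_len(n)) else character(0)
  if (n == 0) {
    empty <- data.frame(lake_id = character(0), trophic_state =
                          as_trophic_state(integer(0)))
    return(structure(list(lakes = empty,
                          design = matrix(numeric(0), 0, 4,
                                          dimnames = list(NULL, .PREDICTORS)),
                          latent = data.frame(eta = numeric(0), z = numeric(0)),
                          truth = truth),
                     class = "synthetic_lakes"))
  }
  out <- .with_seed(seed, {
    if (mode == "standardized") {
      X <- matrix(stats::rnorm(n * 4), n, 4, dimnames = list(ids, .PREDICTORS))
      lakes <- data.frame(lake_id = ids, X, stringsAsFactors = FALSE,
                          row.names = NULL)
    } else {
      rp <- raw_params
      lakes <- data.frame(
        lake_id = ids,
        secchi_m = stats::qlnorm(stats::runif(n), rp$secchi["meanlog"],
                                 rp$secchi["sdlog"]),
        tn_ugl = stats::qlnorm(stats::runif(n), rp$nitrogen["meanlog"],
                               rp$nitrogen["sdlog"]),
        tp_ugl = stats::qlnorm(stats::runif(n), rp$phosphorus["meanlog"],
                               rp$phosphorus["sdlog"]),
        elevation_m = stats::qnorm(stats::runif(n), rp$elevation["mean"],
                                   rp$elevation["sd"]),
        stringsAsFactors = FALSE, row.names = NULL)
      spec <- fit_standardization(lakes)
      X <- apply_standardization(lakes, spec)
    }
    eta <- trophic_index(X, params)
    z <- eta + stats::qlogis(stats::runif(n))
    list(lakes = lakes, X = X, eta = eta, z = z)
  })
  state <- classify_interval(out$z, params)
  out$lakes$trophic_state <- state
  structure(list(lakes = out$lakes, design = out$X,
                 latent = data.frame(eta = out$eta, z = out$z),
                 truth = truth),
            class = "synthetic_lakes")
}

#' @export
print.synthetic_lakes <- function(x, ...) {
  cat("Synthetic lake dataset: n =", nrow(x$lakes),
      "(", x$truth$mode, "mode, seed", x$truth$seed, ")\n")
  if (nrow(x$lakes) > 0) print(table(x$lakes$trophic_state))
  invisible(x)
}

#' Attach noisy single-variable reference classifications
#'
#' Emulates the three classical one-variable trophic classifications
#' (chlorophyll a, total nitrogen, total phosphorus): each copies the true
#' state but, independently with probability `noise_rate`, slips to an
#' adjacent class (up or down with equal probability in the interior;
#' boundary classes can only move inward).  This is the test bed for
#' [consensus_filter()].
#'
#' @param dataset A `synthetic_lakes` object or a lake data.frame with
#'   `trophic_state`.
#' @param noise_rate Per-label perturbation probability in \[0, 1).
#' @param seed Integer seed.
#' @return The lake data.frame with `ref_chla`, `ref_tn`, `ref_tp` added.
#' @export
make_reference_labels <- function(dataset, noise_rate = 0.1, seed = 1L) {
  if (inherits(dataset, "synthetic_lakes")) dataset <- dataset$lakes
  if (!(noise_rate >= 0 && noise_rate < 1)) {
    stop("noise_rate must lie in [0, 1)", call. = FALSE)
  }
  truth <- .state_code(dataset$trophic_state)
  n <- length(truth)
  perturb <- function(k, flip, dir) {
    k2 <- k
    up <- flip & (k == 1 | (k < 4 & dir))
    down <- flip & !up
    k2[up] <- k[up] + 1L
    k2[down] <- k[down] - 1L
    k2
  }
  labs <- .with_seed(seed, {
    lapply(1:3, function(j) {
      flip <- stats::runif(n) < noise_rate
      dir <- stats::runif(n) < 0.5
      as_trophic_state(perturb(truth, flip, dir))
    })
  })
  dataset$ref_chla <- labs[[1]]
  dataset$ref_tn <- labs[[2]]
  dataset$ref_tp <- labs[[3]]
  dataset
}
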