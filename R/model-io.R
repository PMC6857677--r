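# JSON serialization of fitted models.  Numbers are written with 17
# significant digits so that a write/read cycle reproduces every double
# bit-exactly.

#' Write a trophic state model to a JSON file
#'
#' Serializes coefficients, cutpoints, the standardization spec, standard
#' errors when available, and fit metadata (method, seed, n, log-likelihood,
#' package version, timestamp).
#'
#' @param model A `trophic_model` (from [fit_trophic_model()]) or a bare
#'   `polr_params` object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_polr_model <- function(model, path) {
  if (inherits(model, "polr_params")) {
    model <- structure(list(params = model), class = "trophic_model")
  }
  stopifnot(inherits(model, "trophic_model"))
  p <- model$params
  obj <- list(
    coefficients = as.list(p$coefficients),
    cutpoints = unname(p$cutpoints),
    latent_scale = p$latent_scale
  )
  if (!is.null(model$standardization)) {
    s <- model$standardization
    obj$standardization <- list(center = as.list(s$center),
                                scale = as.list(s$scale),
                                log_transformed = as.list(s$log_transformed))
  }
  if (!is.null(model$se)) obj$se <- as.list(model$se)
  meta <- model$meta
  if (is.null(meta)) meta <- list()
  meta$version <- as.character(utils::packageVersion("trophicstate"))
  if (is.null(meta$timestamp)) {
    meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  }
  obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

#' Read a trophic state model from a JSON file
#'
#' @param path Path to a model file written by [write_polr_model()].
#' @return A `trophic_model` object.
#' @export
read_polr_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- polr_params(unlist(obj$coefficients), obj$cutpoints,
                        latent_scale = obj$latent_scale %||% 1)
  std <- NULL
  if (!is.null(obj$standardization)) {
    std <- structure(list(center = unlist(obj$standardization$center),
                          scale = unlist(obj$standardization$scale),
                          log_transformed = unlist(obj$standardization$log_transformed)),
                     class = "standardization_spec")
  }
  structure(list(params = params, standardization = std,
                 se = if (!is.null(obj$se)) unlist(obj$se),
                 meta = obj$meta),
            class = "trophic_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trophic_model <- function(x, ...) {
  print(x$params)
  if (!is.null(x$standardization)) {
    cat("Standardization fitted on n =", x$meta$n %||% "?", "lakes\n")
  }
  if (!is.null(x$meta$method)) {
    cat("Fit method:", x$meta$method,
        " log-likelihood:", format(x$meta$log_likelihood), "\n")
  }
  invisible(x)
}
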