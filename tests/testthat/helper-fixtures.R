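# Shared fixtures, generated in code.

# small raw-scale lake table with plausible NLA-like values
make_test_lakes <- function(n = 12, seed = 101) {
  set.seed(seed)
  data.frame(
    lake_id = sprintf("L%03d", seq_len(n)),
    secchi_m = round(rlnorm(n, log(2), 0.8), 3),
    tn_ugl = round(rlnorm(n, log(600), 0.9), 1),
    tp_ugl = round(rlnorm(n, log(30), 1.0), 1),
    elevation_m = round(rnorm(n, 400, 300), 1),
    stringsAsFactors = FALSE
  )
}

write_lakes_csv <- function(lakes, path = tempfile(fileext = ".csv")) {
  write.csv(lakes, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# confusion matrix of the published national hold-out evaluation
# (rows actual, columns predicted)
national_confusion <- function() {
  matrix(c(7, 1, 0, 0,
           1, 14, 9, 2,
           0, 0, 16, 8,
           0, 1, 4, 10),
         nrow = 4, byrow = TRUE,
         dimnames = list(actual = trophic_levels(),
                         predicted = trophic_levels()))
}

# quadrature oracle: class probability as numeric integral of the logistic
# density with location eta over the cutpoint interval
quadrature_class_prob <- function(eta, cutpoints, k) {
  lims <- c(-Inf, cutpoints, Inf)
  stats::integrate(stats::dlogis, lower = lims[k], upper = lims[k + 1],
                   location = eta, rel.tol = 1e-12)$value
}

# analytic accuracy of the interval classifier under the generating model
# with eta ~ N(0, |A|): E_eta[ p_{k*(eta)}(eta) ]
analytic_interval_accuracy <- function(params) {
  s <- sqrt(sum(params$coefficients^2))
  integrand <- function(eta) {
    k <- as.integer(classify_interval(eta, params))
    p <- class_probabilities(eta, params)
    p[cbind(seq_along(eta), k)] * dnorm(eta, 0, s)
  }
  cuts <- params$cutpoints
  # integrate piecewise so the kink at each cutpoint is respected
  lims <- c(-Inf, cuts, Inf)
  sum(vapply(1:4, function(i) {
    stats::integrate(integrand, lims[i], lims[i + 1], rel.tol = 1e-10)$value
  }, 0))
}
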