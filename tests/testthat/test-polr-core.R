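# The ordinal model math: index, probabilities, classifiers, likelihood.

national <- nla_polr_params()

test_that("trophic_index is the standardized linear predictor", {
  expect_equal(trophic_index(c(0, 0, 0, 0), national), 0)
  expect_equal(trophic_index(c(1, 0, 0, 0), national), -1.69)
  expect_equal(trophic_index(c(0, 1, 1, 0), national), 0.69 + 0.55)
  X <- rbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  expect_equal(trophic_index(X, national), c(-1.69, -0.56))
  expect_error(trophic_index(c(1, 2, 3), national), "4 columns")
})

test_that("exceedance probability follows the shifted logistic CDF", {
  for (k in 1:3) {
    expect_equal(exceedance_probability(national$cutpoints[[k]], k, national), 0.5)
    expect_equal(
      exceedance_probability(national$cutpoints[[k]] + log(9), k, national), 0.9)
  }
  expect_equal(exceedance_probability(1e4, 2, national), 1)
  expect_equal(exceedance_probability(-1e4, 2, national), 0)
  expect_equal(exceedance_probability(0.3, 0, national), 1)
  expect_equal(exceedance_probability(0.3, 4, national), 0)
})

test_that("class probabilities telescope from exceedances and match the CDF", {
  p <- polr_params(rep(0, 4), c(-1, 0, 1))
  F <- plogis
  expect_equal(unname(class_probabilities(0, p)[1, ]),
               c(F(-1), F(0) - F(-1), F(1) - F(0), 1 - F(1)))
  # at the first cutpoint, mass at or below oligotrophic is exactly one half
  expect_equal(unname(class_probabilities(national$cutpoints[[1]],
                                          national)[1, 1]), 0.5)
})

test_that("class probabilities and log-likelihood agree with a quadrature oracle", {
  set.seed(42)
  for (rep in 1:20) {
    cuts <- sort(rnorm(3, sd = 3))
    if (min(diff(cuts)) < 0.1) cuts <- cuts + c(-0.2, 0, 0.2)
    pars <- polr_params(rnorm(4), cuts)
    eta <- runif(1, -12, 12)
    probs <- class_probabilities(eta, pars)[1, ]
    for (k in 1:4) {
      expect_equal(unname(probs[k]),
                   quadrature_class_prob(eta, pars$cutpoints, k),
                   tolerance = 1e-8)
    }
  }
  # single-observation log-likelihood: closed-form logistic CDF difference
  p <- polr_params(c(1, 0, 0, 0), c(-1, 0, 1))
  X <- matrix(c(0, 0, 0, 0), 1)
  expect_equal(polr_log_likelihood(p, X, "mesotrophic"),
               log(plogis(0) - plogis(-1)))
})

test_that("log-likelihood is exchangeable, stable at extreme indices, -Inf at zero mass", {
  set.seed(5)
  X <- matrix(rnorm(40), 10, 4)
  y <- as_trophic_state(sample(1:4, 10, replace = TRUE))
  perm <- sample(10)
  expect_equal(polr_log_likelihood(national, X, y),
               polr_log_likelihood(national, X[perm, ], y[perm]))

  # no catastrophic cancellation out to |eta| = 30; closed-form oracle uses
  # the reflected logistic CDF so the reference is itself accurate in tails
  p <- polr_params(c(1, 0, 0, 0), c(-1, 0, 1))
  closed_form <- function(eta, k) {
    lims <- unname(c(-Inf, p$cutpoints, Inf))
    a <- lims[k + 1] - eta; b <- lims[k] - eta
    # reflect when the interval sits above eta, so both CDF values are small
    if (a + b > 0) log(plogis(-b) - plogis(-a)) else log(plogis(a) - plogis(b))
  }
  for (eta in c(-30, -15, 15, 30)) {
    Xe <- matrix(c(eta, 0, 0, 0), 1)
    for (k in 1:4) {
      got <- polr_log_likelihood(p, Xe, k)
      expect_equal(got, closed_form(eta, k), tolerance = 1e-8)
      expect_false(is.nan(got))
    }
  }
  # an impossible class at working precision yields -Inf, not an error:
  # both interval endpoints of the mesotrophic band have log CDF 0 here
  expect_identical(polr_log_likelihood(p, matrix(c(-800, 0, 0, 0), 1), 2), -Inf)
})

test_that("interval classification assigns boundaries upward", {
  expect_equal(as.character(classify_interval(-4, national)), "oligotrophic")
  expect_equal(as.character(classify_interval(0, national)), "eutrophic")
  expect_equal(as.character(classify_interval(2.62, national)), "hypereutrophic")
  expect_equal(as.character(classify_interval(-3.36, national)), "mesotrophic")
  expect_error(classify_interval(NaN, national), "non-finite")
})

test_that("maximum-probability classification breaks ties downward and tracks intervals", {
  expect_equal(as.character(classify_map(c(0.7, 0.2, 0.08, 0.02))),
               "oligotrophic")
  expect_equal(as.character(classify_map(c(0.5, 0.5, 0, 0))), "oligotrophic")

  # grid oracle: the two classifiers may disagree only in a narrow band
  # adjacent to each cutpoint where the modal class switches
  grid <- seq(-8, 8, by = 0.01)
  map_cls <- as.integer(classify_map(class_probabilities(grid, national)))
  int_cls <- as.integer(classify_interval(grid, national))
  disagree <- grid[map_cls != int_cls]
  expect_gt(length(disagree), 0)
  dist_to_cut <- vapply(disagree,
                        function(g) min(abs(g - national$cutpoints)), 0)
  expect_lt(max(dist_to_cut), 0.2)
})

test_that("probabilities normalize and are stochastically ordered in the index", {
  set.seed(99)
  for (rep in 1:25) {
    pars <- polr_params(rnorm(4), sort(rnorm(3, sd = 2)) + c(-0.3, 0, 0.3))
    eta <- sort(runif(50, -10, 10))
    probs <- class_probabilities(eta, pars)
    expect_equal(rowSums(probs), rep(1, 50), tolerance = 1e-12)
    expect_true(all(probs >= 0 & probs <= 1))
    # Pr(state <= k) strictly decreasing in eta, every k
    for (k in 1:3) {
      cum <- rowSums(probs[, 1:k, drop = FALSE])
      expect_true(all(diff(cum) < 0))
    }
  }
})

test_that("shifting the index and all cutpoints together changes nothing", {
  set.seed(17)
  for (rep in 1:10) {
    pars <- polr_params(rnorm(4), sort(runif(3, -4, 4)))
    delta <- rnorm(1, sd = 5)
    shifted <- polr_params(pars$coefficients, pars$cutpoints + delta)
    eta <- runif(20, -8, 8)
    expect_equal(class_probabilities(eta + delta, shifted),
                 class_probabilities(eta, pars), tolerance = 1e-12)
  }
})

test_that("model files round-trip every double bit-exactly", {
  sim <- simulate_lakes(200, mode = "raw", seed = 31)
  model <- fit_trophic_model(sim$lakes)
  path <- tempfile(fileext = ".json")
  write_polr_model(model, path)
  back <- read_polr_model(path)
  expect_identical(back$params$coefficients, model$params$coefficients)
  expect_identical(unname(back$params$cutpoints), unname(model$params$cutpoints))
  expect_identical(back$standardization$center, model$standardization$center)
  expect_identical(back$standardization$scale, model$standardization$scale)
  expect_identical(unname(back$se), unname(model$se))
  expect_equal(back$meta$method, "mle")
})
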