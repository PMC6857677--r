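# Maximum-likelihood and Bayesian estimation.

test_that("fit_polr_mle matches an independent ordinal-regression implementation", {
  skip_if_not_installed("MASS")
  sim <- simulate_lakes(600, seed = 7)
  fit <- fit_polr_mle(sim$design, sim$lakes$trophic_state)
  d <- data.frame(y = sim$lakes$trophic_state, sim$design)
  ref <- MASS::polr(y ~ secchi + nitrogen + phosphorus + elevation,
                    data = d, Hess = TRUE)
  expect_equal(unname(fit$params$coefficients), unname(coef(ref)),
               tolerance = 1e-4)
  expect_equal(unname(fit$params$cutpoints), unname(ref$zeta),
               tolerance = 1e-4)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-3)
  # and our optimum is at least as good as the reference software's
  ref_params <- polr_params(coef(ref), ref$zeta)
  expect_gte(fit$log_likelihood,
             polr_log_likelihood(ref_params, sim$design,
                                 sim$lakes$trophic_state) - 1e-6)
  expect_true(fit$converged)
})

test_that("a coarse-lattice likelihood search confirms the toy-data optimum", {
  # two informative predictors, n = 40; brute force over a coefficient
  # lattice (cutpoints held at the cumulative-frequency logits)
  set.seed(12)
  X <- cbind(secchi = rnorm(40), nitrogen = rnorm(40),
             phosphorus = rnorm(40), elevation = rnorm(40))
  truth <- polr_params(c(-1, 1, 0, 0), c(-1.5, 0, 1.5))
  eta <- trophic_index(X, truth)
  y <- classify_interval(eta + qlogis(runif(40)), truth)
  while (length(unique(y)) < 4) { # ensure all classes in the toy sample
    y <- classify_interval(eta + qlogis(runif(40)), truth)
  }
  fit <- fit_polr_mle(X, y)
  a_hat <- fit$params$coefficients
  # brute-force slice through the fitted point over the two informative
  # coefficients: no lattice point may beat the reported optimum, and the
  # lattice argmax must sit within one spacing of the fitted values
  lattice <- expand.grid(a1 = seq(-3, 3, by = 0.25),
                         a2 = seq(-3, 3, by = 0.25))
  ll <- apply(lattice, 1, function(r) {
    polr_log_likelihood(polr_params(c(r[1], r[2], a_hat[3], a_hat[4]),
                                    fit$params$cutpoints), X, y)
  })
  expect_true(all(ll <= fit$log_likelihood + 1e-10))
  best <- lattice[which.max(ll), ]
  expect_lt(abs(best$a1 - a_hat[1]), 0.25 + 1e-10)
  expect_lt(abs(best$a2 - a_hat[2]), 0.25 + 1e-10)
})

test_that("degenerate labels and designs are rejected with named diagnoses", {
  sim <- simulate_lakes(100, seed = 3)
  y_const <- rep("eutrophic", 100)
  expect_error(fit_polr_mle(sim$design, y_const), "oligotrophic")
  y3 <- sim$lakes$trophic_state
  y3[y3 == "hypereutrophic"] <- "eutrophic"
  expect_error(fit_polr_mle(sim$design, y3), "hypereutrophic")
  X_const <- sim$design
  X_const[, "phosphorus"] <- 2
  expect_error(fit_polr_mle(X_const, sim$lakes$trophic_state), "phosphorus")
  expect_error(fit_polr_mle(sim$design[1:10, ],
                            sim$lakes$trophic_state[1:10]), "at least 20")
})

test_that("the likelihood at the MLE dominates the generating parameters", {
  for (s in 1:5) {
    sim <- simulate_lakes(400, seed = 100 + s)
    fit <- fit_polr_mle(sim$design, sim$lakes$trophic_state)
    expect_gte(fit$log_likelihood,
               polr_log_likelihood(sim$truth$params, sim$design,
                                   sim$lakes$trophic_state))
  }
})

test_that("permuting design columns permutes coefficients and nothing else", {
  sim <- simulate_lakes(500, seed = 21)
  fit <- fit_polr_mle(sim$design, sim$lakes$trophic_state)
  perm <- c(3, 1, 4, 2)
  Xp <- sim$design[, perm]
  fit_p <- fit_polr_mle(Xp, sim$lakes$trophic_state)
  expect_equal(unname(fit_p$params$coefficients),
               unname(fit$params$coefficients[perm]), tolerance = 1e-6)
  expect_equal(fit_p$params$cutpoints, fit$params$cutpoints, tolerance = 1e-6)
  expect_equal(fit_p$log_likelihood, fit$log_likelihood, tolerance = 1e-8)
})

test_that("posterior sampling is reproducible and concentrates near the MLE", {
  sim <- simulate_lakes(1500, seed = 11)
  y <- sim$lakes$trophic_state
  b <- suppressWarnings(fit_polr_bayes(sim$design, y, chains = 2,
                                       draws = 750, warmup = 500, seed = 5))
  b2 <- suppressWarnings(fit_polr_bayes(sim$design, y, chains = 2,
                                        draws = 750, warmup = 500, seed = 5))
  expect_identical(b$posterior_draws, b2$posterior_draws)
  expect_equal(dim(b$posterior_draws), c(2 * 750, 7))
  # every retained draw respects the cutpoint ordering
  expect_true(all(b$posterior_draws[, 6] > b$posterior_draws[, 5]))
  expect_true(all(b$posterior_draws[, 7] > b$posterior_draws[, 6]))
  m <- fit_polr_mle(sim$design, y)
  expect_equal(unname(c(b$params$coefficients, b$params$cutpoints)),
               unname(c(m$params$coefficients, m$params$cutpoints)),
               tolerance = 0.1)
  expect_true(all(b$se > 0))

  # a very diffuse prior on modest data keeps the posterior near the MLE
  sim_s <- simulate_lakes(300, seed = 13)
  bf <- suppressWarnings(fit_polr_bayes(sim_s$design, sim_s$lakes$trophic_state,
                                        prior_scale = 1e4, chains = 2,
                                        draws = 500, warmup = 500, seed = 2))
  mf <- fit_polr_mle(sim_s$design, sim_s$lakes$trophic_state)
  expect_equal(unname(bf$params$coefficients),
               unname(mf$params$coefficients), tolerance = 0.25)
})
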