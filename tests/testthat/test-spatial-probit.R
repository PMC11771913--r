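quick_mcmc <- function(seed = 1, n_draws = 4000, burn_in = 800) {
  mcmc_config(n_draws = n_draws, burn_in = burn_in, seed = seed)
}

balanced_design <- function(seed, n = 300, rho = 0, beta = c(0, 1)) {
  gen <- generate_crash_table(recovery_config(seed, n_background = n,
                                              rho = rho, beta = beta))
  d <- build_design(gen$table, "z")
  list(design = d, truth = gen$truth,
       W = row_standardize(knn_weights(d$coords, 5)))
}

test_that("intercept-only probit posterior matches the closed-form MLE", {
  set.seed(131)
  y <- rbinom(400, 1, 0.6)
  tab <- data.frame(id = 1:400, x = runif(400), y = runif(400),
                    severity = y, age = 70)
  d <- build_design(tab, character(0))
  fit <- fit_probit(d, quick_mcmc(seed = 3))
  phat <- mean(y)
  s <- fit$summaries
  expect_lt(abs(s$mean[1] - qnorm(phat)), 4 * s$mcse[1] + 0.02)
})

test_that("probit recovers generating coefficients (rho = 0 DGP)", {
  errs <- sapply(1:3, function(k) {
    gen <- generate_crash_table(recovery_config(140 + k, n_background = 500,
                                                rho = 0, beta = c(0.5, -1)))
    d <- build_design(gen$table, "z")
    fit <- fit_probit(d, quick_mcmc(seed = 150 + k))
    fit$summaries$mean[1:2] - c(0.5, -1)
  })
  expect_true(all(abs(rowMeans(errs)) < 0.15))
})

test_that("a zero-information column returns (approximately) its prior", {
  set.seed(161)
  y <- rbinom(300, 1, 0.5)
  tab <- data.frame(id = 1:300, x = runif(300), y = runif(300),
                    severity = y, age = 70, dead = 0)
  d <- build_design(tab, "dead")
  fit <- fit_probit(d, mcmc_config(n_draws = 8000, burn_in = 1000, seed = 5))
  s <- fit$summaries[fit$summaries$parameter == "dead", ]
  # prior is N(0, 100): mean near 0, sd near 10
  expect_lt(abs(s$mean), 1.5)
  expect_gt(s$sd, 7)
  expect_lt(s$sd, 13)
})

test_that("degenerate responses are refused", {
  tab <- data.frame(id = 1:10, x = 1:10, y = 1:10, severity = 1L, age = 70,
                    z = rnorm(10))
  d <- build_design(tab, "z")
  expect_error(fit_probit(d, quick_mcmc()), "all-1")
  expect_error(fit_spatial_probit(d, row_standardize(knn_weights(d$coords, 3)),
                                  quick_mcmc()), "all-1")
})

test_that("spatial sampler conditionals reduce to plain probit at rho = 0", {
  set.seed(167)
  n <- 50
  X <- cbind(1, rnorm(n))
  beta <- c(0.3, -0.8)
  ystar <- rnorm(n)
  W <- row_standardize(knn_weights(data.frame(x = runif(n), y = runif(n)), 5))
  cond <- crashspot:::sar_latent_conditionals(ystar, X, beta, 0, W$W)
  expect_equal(cond$mean, drop(X %*% beta), tolerance = 1e-12)
  expect_equal(cond$var, rep(1, n), tolerance = 1e-12)
  # and at rho != 0 the variance must differ (spatial mixing present)
  cond2 <- crashspot:::sar_latent_conditionals(ystar, X, beta, 0.5, W$W)
  expect_false(isTRUE(all.equal(cond2$var, rep(1, n))))
})

test_that("spatial fit enforces its contracts", {
  b <- balanced_design(171, n = 150)
  # unstandardised weights refused
  Wu <- knn_weights(b$design$coords, 5)
  expect_error(fit_spatial_probit(b$design, Wu, quick_mcmc()),
               "row-standardized")
  fit <- fit_spatial_probit(b$design, b$W, quick_mcmc(seed = 7))
  # every retained rho draw strictly inside the support
  expect_true(all(fit$rho_draws > b$W$rho_support[1] &
                  fit$rho_draws < b$W$rho_support[2]))
  # latent-sign consistency held at every retained draw
  expect_true(fit$latent_sign_ok)
  expect_gt(fit$acceptance_rate, 0.05)
  expect_lt(fit$acceptance_rate, 0.95)
})

test_that("identical seed and config give identical draw streams", {
  b <- balanced_design(181, n = 120)
  f1 <- fit_probit(b$design, quick_mcmc(seed = 11, n_draws = 1500, burn_in = 300))
  f2 <- fit_probit(b$design, quick_mcmc(seed = 11, n_draws = 1500, burn_in = 300))
  expect_identical(f1$beta_draws, f2$beta_draws)
  s1 <- fit_spatial_probit(b$design, b$W,
                           quick_mcmc(seed = 11, n_draws = 1500, burn_in = 300))
  s2 <- fit_spatial_probit(b$design, b$W,
                           quick_mcmc(seed = 11, n_draws = 1500, burn_in = 300))
  expect_identical(s1$beta_draws, s2$beta_draws)
  expect_identical(s1$rho_draws, s2$rho_draws)
  s3 <- fit_spatial_probit(b$design, b$W,
                           quick_mcmc(seed = 12, n_draws = 1500, burn_in = 300))
  expect_false(identical(s1$rho_draws, s3$rho_draws))
})

test_that("posterior summaries: degenerate, known-quantile and quantile-identity cases", {
  mk_fit <- function(draws) {
    crashspot:::new_posterior_fit(draws, NULL, "probit", quick_mcmc(),
                                  n_obs = 10)
  }
  const <- mk_fit(matrix(2, nrow = 200, ncol = 1,
                         dimnames = list(NULL, "c")))
  s <- const$summaries
  expect_equal(s$sd, 0)
  expect_equal(s$mcse, 0)
  expect_equal(s$bci_lower, 2)
  expect_equal(s$bci_upper, 2)

  set.seed(191)
  z <- matrix(rnorm(10000), dimnames = list(NULL, "z"))
  sz <- mk_fit(z)$summaries
  expect_lt(abs(sz$mean), 0.05)
  expect_lt(abs(sz$sd - 1), 0.05)
  expect_lt(abs(sz$bci_lower - (-1.96)), 0.05)
  expect_lt(abs(sz$bci_upper - 1.96), 0.05)
  # interval endpoints are exactly the empirical equal-tail quantiles
  expect_equal(sz$bci_lower, unname(quantile(z, 0.025)))
  expect_equal(sz$bci_upper, unname(quantile(z, 0.975)))
})

test_that("DIC closed forms and the perfect-fit limit", {
  # balanced intercept-only: deviance at the posterior mean ~ -2 n ln(1/2)
  set.seed(197)
  y <- rep(c(0L, 1L), 150)
  tab <- data.frame(id = seq_along(y), x = runif(300), y = runif(300),
                    severity = y, age = 70)
  d <- build_design(tab, character(0))
  fit <- fit_probit(d, quick_mcmc(seed = 13))
  dic <- compute_dic(fit, d)
  expect_lt(abs(dic$dhat - (-2 * 300 * log(0.5))), 2)
  expect_equal(dic$dic, dic$dbar + dic$pd, tolerance = 1e-12)
  expect_equal(dic$pd, dic$dbar - dic$dhat, tolerance = 1e-12)

  # perfect-fit limit: probabilities at the observed outcomes -> deviance 0
  expect_equal(crashspot:::binary_deviance(y, ifelse(y == 1, 1 - 1e-13, 1e-13)),
               0, tolerance = 1e-6)
})

test_that("marginal effects: registry arithmetic, zero coefficient, rho = 0 equivalence", {
  mk_fit <- function(draws) {
    crashspot:::new_posterior_fit(draws, NULL, "probit", quick_mcmc(),
                                  n_obs = 3)
  }
  tab <- data.frame(id = 1:3, x = 1:3, y = 1:3, severity = c(0L, 1L, 0L),
                    age = 70, v = c(1, 2, 3))
  d <- build_design(tab, "v")
  # constant coefficient -0.106 reports as -10.6% in registry mode
  draws <- matrix(rep(c(0.5, -0.106), each = 200), ncol = 2,
                  dimnames = list(NULL, c("(Intercept)", "v")))
  me <- marginal_effects(mk_fit(draws), d)
  expect_equal(me$paper_pct[me$parameter == "v"], -10.6)
  # all-zero draws: both modes report 0
  zero <- matrix(0, 200, 2, dimnames = list(NULL, c("(Intercept)", "v")))
  me0 <- marginal_effects(mk_fit(zero), d)
  expect_true(all(me0$paper_pct == 0))
  expect_true(all(me0$ape == 0))

  # on a rho = 0 fixture, spatial and non-spatial APEs coincide within MC error
  b <- balanced_design(211, n = 250)
  fp <- fit_probit(b$design, quick_mcmc(seed = 17))
  fs <- fit_spatial_probit(b$design, b$W, quick_mcmc(seed = 17))
  mep <- marginal_effects(fp, b$design)
  mes <- marginal_effects(fs, b$design, b$W)
  expect_lt(abs(mep$ape[2] - mes$ape[2]), 0.05)
  # requesting the spatial multiplier without W fails loudly
  expect_error(marginal_effects(fs, b$design), "weight matrix")
})

test_that("stepwise pruning removes noise and keeps signal", {
  set.seed(223)
  n <- 400
  z <- rnorm(n)                      # strong signal
  junk <- rnorm(n)                   # pure noise
  eta <- 0.2 + 1.2 * z
  y <- as.integer(eta + rnorm(n) > 0)
  tab <- data.frame(id = 1:n, x = runif(n), y = runif(n), severity = y,
                    age = 70, z = z, junk = junk)
  d <- build_design(tab, c("z", "junk"))
  pr <- stepwise_prune(d, NULL, quick_mcmc(seed = 19))
  expect_identical(pr$removal_log$parameter, "junk")
  expect_true("z" %in% colnames(pr$design$X))
  expect_true(all(pr$fit$summaries$significant[
    pr$fit$summaries$parameter != "(Intercept)"]))
  # bookkeeping: removals = initial predictors - retained predictors
  expect_equal(nrow(pr$removal_log), ncol(d$X) - ncol(pr$design$X))

  # all-significant design: zero removals
  d2 <- build_design(tab, "z")
  pr2 <- stepwise_prune(d2, NULL, quick_mcmc(seed = 23))
  expect_equal(nrow(pr2$removal_log), 0)
})

test_that("rho credible intervals are calibrated at the null (scaled down)", {
  # 12 replicates at n = 250: the 95% interval should cover rho = 0 in
  # most replicates (allow two misses)
  covered <- sapply(1:12, function(k) {
    b <- balanced_design(230 + k, n = 250)
    fit <- fit_spatial_probit(b$design, b$W, quick_mcmc(seed = 330 + k))
    q <- quantile(fit$rho_draws, c(0.025, 0.975))
    q[1] <= 0 && 0 <= q[2]
  })
  expect_gte(sum(covered), 10)
})

test_that("fit report and trace files are written and readable", {
  b <- balanced_design(241, n = 120)
  fit <- fit_spatial_probit(b$design, b$W,
                            quick_mcmc(seed = 29, n_draws = 1200, burn_in = 200))
  dic <- suppressMessages(compute_dic(fit, b$design, b$W))
  td <- withr::local_tempdir()
  rp <- file.path(td, "report.txt")
  write_fit_report(fit, dic, rp)
  txt <- readLines(rp)
  expect_true(any(grepl("spatial lag binary probit", txt)))
  expect_true(any(grepl("DIC:", txt)))
  tr <- file.path(td, "trace.tsv")
  write_trace(fit, tr)
  tdf <- read.delim(tr)
  expect_equal(nrow(tdf), nrow(fit$beta_draws))
  expect_true("rho" %in% names(tdf))
})
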