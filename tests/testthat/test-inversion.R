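# Nighttime E0 estimation, likelihoods, DE-MC sampler, diagnostics.

test_that("nighttime E0 fit recovers noise-free truth to 4 significant digits", {
  s <- site_scenario("GRA", n_days = 10, seed = 1, sigma_nee = 0, sigma_cos = 0,
                     true_resp = respiration_params(3, 150))
  camp <- simulate_campaign(s)
  est <- fit_e0_nighttime(camp)
  expect_equal(est$e0, 150, tolerance = 1e-4)
  expect_equal(est$rb_night, 3, tolerance = 1e-4)
  expect_lt(est$rmse, 1e-6)
})

test_that("nighttime E0 fit is unbiased over repeated noisy simulations", {
  # repeated-simulation oracle: 100 campaigns, sigma_NEE = 0.5, ~500 nights
  set.seed(99)
  t_ref <- 15; t0 <- -46.02
  errs <- replicate(100, {
    t_air <- runif(500, 4, 16)
    reco <- 3 * exp(150 * (1 / (t_ref - t0) - 1 / (t_air - t0)))
    d <- tibble::tibble(nee = reco + rnorm(500, 0, 0.5), par = 0, t_air = t_air)
    fit_e0_nighttime(d)$e0 - 150
  })
  expect_lt(abs(mean(errs)), 15)
})

test_that("degenerate nighttime designs are rejected", {
  d <- tibble::tibble(nee = rnorm(100, 3, 0.1), par = 0, t_air = 10)
  expect_error(fit_e0_nighttime(d), "isothermal|unidentifiable")
  expect_error(fit_e0_nighttime(d[1:10, ]), "nighttime records")
})

test_that("FP likelihood matches a hand-summed Gaussian log-density", {
  d <- tibble::tibble(
    nee = c(-8, -11, -3, -14, -6), par = c(300, 800, 100, 1500, 200),
    t_air = c(18, 22, 15, 25, 17))
  theta <- c(alpha = 0.05, beta = 20, rb = 2, sigma_nee = 1.5)
  e0 <- 120
  # independent spreadsheet-style evaluation, term by term
  gpp <- 0.05 * 20 * d$par / (0.05 * d$par + 20)
  reco <- 2 * exp(120 * (1 / 61.02 - 1 / (d$t_air + 46.02)))
  expected <- sum(dnorm(d$nee, reco - gpp, 1.5, log = TRUE))
  expect_equal(loglik_fp(theta, e0, d), expected, tolerance = 1e-12)
  # doubling the residuals at fixed sigma lowers the likelihood
  d2 <- dplyr::mutate(d, nee = (reco - gpp) + 2 * (nee - (reco - gpp)))
  expect_lt(loglik_fp(theta, e0, d2), loglik_fp(theta, e0, d))
  expect_error(loglik_fp(theta, e0, dplyr::mutate(d, par = 0)), "daytime")
})

test_that("FP+ likelihood is the sum of two independent stream densities", {
  d <- tibble::tibble(
    nee = c(-8, -11, -3, -14, -6), par = c(300, 800, 100, 1500, 200),
    t_air = c(18, 22, 15, 25, 17),
    fcos_canopy = c(-25, -32, -12, -40, -20),
    chi_co2 = 400, chi_cos = 500)
  theta <- c(alpha = 0.05, beta = 20, rb = 2, iota = 1.7, kappa = 50,
             sigma_nee = 1.5, sigma_cos = 4)
  e0 <- 120
  gpp <- 0.05 * 20 * d$par / (0.05 * d$par + 20)
  reco <- 2 * exp(120 * (1 / 61.02 - 1 / (d$t_air + 46.02)))
  fcos_model <- -(gpp * 1.7 * exp(50 / d$par) / 8e5 * 1e6)
  expected <- sum(dnorm(d$nee, reco - gpp, 1.5, log = TRUE)) +
    sum(dnorm(d$fcos_canopy, fcos_model, 4, log = TRUE))
  expect_equal(loglik_fpplus(theta, e0, d), expected, tolerance = 1e-12)
})

test_that("standardized residuals at generator truth have unit variance", {
  s <- site_scenario("GRA", n_days = 90, seed = 13)
  camp <- simulate_campaign(s)
  camp$fcos_canopy <- camp$fcos_eco - camp$true_f_soil
  day <- camp |> dplyr::filter(par > 10)
  expect_gt(nrow(day), 2000)
  z_nee <- (day$nee - day$true_nee) / s$sigma_nee
  z_cos <- (day$fcos_canopy - day$true_fcos_canopy) / s$sigma_cos
  expect_equal(var(z_nee), 1, tolerance = 0.05)
  expect_equal(var(z_cos), 1, tolerance = 0.05)
})

test_that("truth parameters beat perturbed parameters on noise-free data", {
  s <- site_scenario("GRA", n_days = 6, seed = 2, sigma_nee = 0, sigma_cos = 0)
  camp <- simulate_campaign(s)
  camp$fcos_canopy <- camp$fcos_eco - camp$true_f_soil
  truth <- c(alpha = 0.05, beta = 30, rb = 4, iota = 1.02, kappa = 50,
             sigma_nee = 0.5, sigma_cos = 1)
  # E0 at truth: noise-free nights identify it exactly
  e0 <- fit_e0_nighttime(camp)$e0
  base <- loglik_fpplus(truth, e0, camp)
  for (p in c("alpha", "beta", "rb", "iota")) {
    up <- truth; up[p] <- up[p] * 1.2
    expect_lt(loglik_fpplus(up, e0, camp), base)
  }
})

test_that("the DE-MC sampler reproduces an analytic 2-D Gaussian target", {
  pr <- prior_spec("fp", overrides = list(
    alpha = list(dist = "uniform", p1 = -50, p2 = 50, lower = -50, upper = 50),
    beta = list(dist = "uniform", p1 = -50, p2 = 50, lower = -50, upper = 50)))
  pr <- pr[1:2, ]
  class(pr) <- c("prior_spec", class(tibble::tibble()))
  mu <- c(10, -5); sds <- c(2, 3); rho <- 0.5
  si <- solve(diag(sds) %*% matrix(c(1, rho, rho, 1), 2) %*% diag(sds))
  ll <- function(th) {
    d <- c(th[["alpha"]], th[["beta"]]) - mu
    -0.5 * drop(d %*% si %*% d)
  }
  ch <- sample_posterior(ll, pr, n_chains = 6, n_iter = 6000, seed = 42,
                         min_retained = 15000)
  d <- tidy(ch) |> dplyr::filter(retained)
  expect_true(ch$converged)
  expect_equal(mean(d$alpha), 10, tolerance = 0.03)
  expect_equal(mean(d$beta), -5, tolerance = 0.03)
  expect_equal(sd(d$alpha), 2, tolerance = 0.05)
  expect_equal(sd(d$beta), 3, tolerance = 0.05)
  expect_equal(cor(d$alpha, d$beta), 0.5, tolerance = 0.05)
  # moment error shrinks with draw count (1/sqrt(n) scaling, loose check)
  ch_small <- sample_posterior(ll, pr, n_chains = 6, n_iter = 300, seed = 42,
                               min_retained = 600)
  err_small <- abs(mean(tidy(ch_small) |> dplyr::filter(retained) |>
                          dplyr::pull(alpha)) - 10)
  err_large <- abs(mean(d$alpha) - 10)
  expect_lt(err_large, err_small + 0.05)
})

test_that("a flat likelihood returns the prior and identical seeds identical chains", {
  pr <- prior_spec("fp")[1:1, ]
  class(pr) <- c("prior_spec", class(tibble::tibble()))
  flat <- function(th) 0
  ch1 <- sample_posterior(flat, pr, n_chains = 4, n_iter = 3000, seed = 7,
                          min_retained = 1000)
  ch2 <- sample_posterior(flat, pr, n_chains = 4, n_iter = 3000, seed = 7,
                          min_retained = 1000)
  expect_identical(ch1$samples, ch2$samples)
  u <- tidy(ch1) |> dplyr::filter(retained) |> dplyr::pull("alpha")
  u <- u[seq(1, length(u), by = 23)] # thin to de-autocorrelate
  ks <- suppressWarnings(stats::ks.test(u, "punif", pr$lower, pr$upper))
  expect_gt(ks$p.value, 0.01)
  expect_error(sample_posterior(flat, prior_spec("fpplus"), n_chains = 5),
               "chains")
})

test_that("Gelman-Rubin is 1 on duplicated chains and small on mixed draws", {
  set.seed(3)
  copies <- rnorm(5000)
  arr <- array(NA_real_, c(3, 5000, 1), dimnames = list(NULL, NULL, "x"))
  for (j in 1:3) arr[j, , 1] <- copies
  expect_equal(unname(gelman_rubin(arr)), 1, tolerance = 1e-3)
  indep <- array(rnorm(4 * 10000), c(4, 10000, 1), dimnames = list(NULL, NULL, "x"))
  expect_lt(gelman_rubin(indep), 1.01)
})

test_that("Gelman-Rubin flags chains stuck at different means", {
  set.seed(4)
  arr <- array(NA_real_, c(2, 1000, 1), dimnames = list(NULL, NULL, "x"))
  arr[1, , 1] <- rnorm(1000, 0)
  arr[2, , 1] <- rnorm(1000, 10)
  # closed-form: B/n ~ 50, W ~ 1 -> R-hat ~ sqrt(51) >> 1.1
  expect_gt(gelman_rubin(arr), 5)
  expect_error(gelman_rubin(arr[1, , , drop = FALSE]), "2 chains")
})

test_that("posterior summaries match analytic quantiles and locate the mode", {
  set.seed(5)
  n <- 25000
  draws <- lapply(1:4, function(i) matrix(rnorm(n), ncol = 1,
                                          dimnames = list(NULL, "x")))
  lp <- do.call(rbind, lapply(draws, function(m) dnorm(m[, 1], log = TRUE)))
  ch <- make_chains(draws, log_post = lp)
  fr <- posterior_summary(ch)
  expect_equal(fr$summary$ci_lo, -1.96, tolerance = 0.02)
  expect_equal(fr$summary$ci_hi, 1.96, tolerance = 0.02)
  expect_equal(fr$summary$median, fr$summary$mean, tolerance = 0.02)
  expect_lt(abs(fr$map), 0.05) # MAP of N(0,1) draws sits near 0
  expect_true(fr$converged)
  expect_equal(fr$n_retained, 4 * n)
})
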