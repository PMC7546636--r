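test_that("GP density matches closed forms and integrates to one", {
  expect_equal(gp_pdf(0, mu = 0, k = 0, sigma = 2), 0.5)   # exponential limit
  expect_equal(gp_pdf(0, mu = 0, k = 1, sigma = 1), 1)     # (1+x)^-2 at 0
  expect_warning(d <- gp_pdf(-1, mu = 0, k = 0.5, sigma = 1), "support")
  expect_equal(d, 0)
  expect_error(gp_pdf(1, 0, 0.5, -1), class = "rubeoscan_error_param")

  for (par in list(c(0.0869, 0.0001), c(1.1599, 0.0004),
                   c(-0.378, 0.156), c(-0.811, 0.916))) {
    k <- par[1]; s <- par[2]
    upper <- if (k < 0) -s / k else Inf
    int <- integrate(function(x) gp_pdf(x, 0, k, s), 0, upper,
                     rel.tol = 1e-9)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
})

test_that("GP tail fitting recovers shapes across the sign range", {
  x <- withr::with_seed(11, rgp(1e4, k = 0.0869, sigma = 1e-4))
  fit <- fit_gp_tail(x, threshold_quantile = 0)
  expect_lt(abs(fit$k - 0.0869), 0.05)
  expect_equal(sgn_k_verdict(fit), "SOC_powerlaw")

  # thresholding preserves the shape (exceedances of a GPD are GPD)
  fit9 <- fit_gp_tail(x, threshold_quantile = 0.9)
  expect_equal(fit9$n_tail, 1000)
  expect_lt(abs(fit9$k - 0.0869), 0.12)

  xn <- withr::with_seed(12, rgp(1e4, k = -0.378, sigma = 0.156))
  expect_lte(max(xn), 0.156 / 0.378)     # finite support bound
  fitn <- fit_gp_tail(xn, threshold_quantile = 0)
  expect_lt(fitn$k, 0)
  expect_lt(abs(fitn$k - (-0.378)), 0.05)
  expect_equal(sgn_k_verdict(fitn), "TW_random")

  xe <- withr::with_seed(13, rexp(1e4))
  fite <- fit_gp_tail(xe, threshold_quantile = 0)
  expect_equal(fite$k, 0, tolerance = 0.05)

  expect_error(fit_gp_tail(rexp(50), threshold_quantile = 0.9),
               class = "rubeoscan_error_fit")
})

test_that("Gamma fitting recovers shape and rate under the rate parametrization", {
  x <- withr::with_seed(21, rgamma(1e4, shape = 5.449, rate = 0.022))
  fit <- fit_gamma(x)
  expect_lt(abs(fit$beta - 5.449) / 5.449, 0.05)
  expect_equal(mean(x), fit$beta / fit$theta, tolerance = 0.01)

  # 3 Monte-Carlo standard errors via the asymptotic Fisher information
  se <- sqrt(1 / (1e4 * (trigamma(5.449) - 1 / 5.449)))
  expect_lt(abs(fit$beta - 5.449), 3 * se)

  xe <- withr::with_seed(22, rexp(1e4, rate = 0.5))
  fite <- fit_gamma(xe)
  expect_equal(fite$beta, 1, tolerance = 0.05)
  expect_equal(fite$theta, 0.5, tolerance = 0.05)

  expect_error(fit_gamma(c(-1, rexp(100))), class = "rubeoscan_error_input")
})

test_that("power-law MLE matches its closed form and printed exponents", {
  n <- 50
  all_e <- rep(exp(1), n)
  fit <- fit_powerlaw(all_e, x_min = 1)
  expect_equal(fit$gamma, -2)            # 1 + N/N, negated

  x <- withr::with_seed(31, rplaw(1e5, exponent = 1.53, x_min = 1))
  fit2 <- fit_powerlaw(x, x_min = 1)
  expect_equal(fit2$gamma, -1.53, tolerance = 0.02)

  expect_error(fit_powerlaw(rep(2, 50), x_min = 2),
               class = "rubeoscan_error_fit")
  expect_message(fit_powerlaw(c(0.5, x[1:100]), x_min = 1), "Excluding")
})

test_that("power-law estimator error shrinks as O(1/N)", {
  est <- function(n, seeds) {
    vapply(seeds, function(s) {
      -fit_powerlaw(withr::with_seed(s, rplaw(n, 1.5, 1)), x_min = 1)$gamma
    }, numeric(1))
  }
  small <- est(1e3, 1:100)
  large <- est(1e5, 1:25)
  expect_lt(abs(mean(large) - 1.5), abs(mean(small) - 1.5) + 0.003)
  expect_lt(sd(large), sd(small))
})

test_that("automatic x_min keeps control-range exponents in band", {
  for (g in c(1.25, 1.40, 1.53)) {
    x <- withr::with_seed(round(100 * g), rplaw(5000, exponent = g, x_min = 1))
    fit <- fit_powerlaw(x, x_min = "auto")
    expect_gte(fit$gamma, -1.55)
    expect_lte(fit$gamma, -1.15)
    expect_gte(fit$n_tail, 10)
  }
})

test_that("the sgn(k) verdict applies the stated boundary convention", {
  expect_equal(sgn_k_verdict(0.0869), "SOC_powerlaw")
  expect_equal(sgn_k_verdict(-0.378), "TW_random")
  expect_equal(sgn_k_verdict(0), "SOC_powerlaw")
  expect_error(sgn_k_verdict(list(sigma = 1)), class = "rubeoscan_error_param")
})

test_that("fit_tails assembles the conditional report", {
  xg <- withr::with_seed(41, rgamma(2000, 4.344, rate = 0.023))
  rep_dm <- fit_tails(xg, threshold_quantile = 0)
  expect_equal(rep_dm$verdict, "TW_random")
  expect_false(is.na(rep_dm$beta))
  expect_true(is.na(rep_dm$gamma))
  expect_equal(rep_dm$beta, 4.344, tolerance = 0.2)

  xp <- withr::with_seed(42, rgp(2000, k = 0.4382, sigma = 0.0033))
  rep_c <- fit_tails(xp, threshold_quantile = 0)
  expect_equal(rep_c$verdict, "SOC_powerlaw")
  expect_true(is.na(rep_c$beta))
  expect_false(is.na(rep_c$gamma))

  td <- tidy(rep_c)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(glance(rep_c)$verdict, "SOC_powerlaw")
})
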