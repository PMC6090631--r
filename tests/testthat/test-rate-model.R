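test_that("the rate prediction evaluates the saturating form exactly", {
  p <- rate_params()
  # never-studied gene in an empty field: basal rate only
  expect_equal(predict_rate(p, 0, 0), 0.00288)
  # cohort mean at the saturation scale halves the numerator, any exponent
  for (a in c(0.5, 1.67, 4)) {
    pa <- rate_params(alpha = a)
    num <- 0.0214 * 24.1 + 0.225 * 7 + 0.00288
    expect_equal(predict_rate(pa, 24.1, 7), num / 2)
  }
  # direct evaluation at arbitrary inputs
  expect_equal(predict_rate(p, 24.1, 10),
               (0.0214 * 24.1 + 0.225 * 10 + 0.00288) / 2)
  ps <- 13.7; pi <- 42
  expect_equal(predict_rate(p, ps, pi),
               (0.0214 * ps + 0.225 * pi + 0.00288) / (1 + (ps / 24.1)^1.67))
  expect_error(predict_rate(p, -1, 0), "non-negative")
  # monotone in the gene's own cumulative count; cohort -> 0 limit
  expect_true(all(diff(predict_rate(p, rep(2, 5), 1:5)) > 0))
  expect_equal(predict_rate(p, 0, 6), 0.225 * 6 + 0.00288)
})

test_that("the Poisson log-likelihood matches term-by-term summation", {
  # single gene-year with mean = count = 1: log pmf = -1
  h1 <- pub_history(matrix(1L, 1, 1, dimnames = list("1", 2000)), 2000L,
                    baseline = 0)
  p1 <- rate_params(k1 = 1e-9, k2 = 0.5, k3 = 1, P_S = 100, alpha = 1)
  expect_equal(log_likelihood(p1, h1, cohort = c(`1999` = 0),
                              fit_years = c(2000, 2000)), -1)

  # random small instance against an explicit loop
  set.seed(66)
  n <- 12; years <- 1995:2004
  counts <- matrix(rpois(n * 10, 1.2), n, dimnames = list(1:n, years))
  h <- pub_history(counts, years, baseline = rpois(n, 2))
  p <- rate_params(0.03, 0.21, 0.01, 18, 1.5)
  ll_loop <- 0
  for (g in 1:n) {
    for (y in years) {
      p_prev <- unname(cum_at(h, y - 1)[as.character(g)])
      ps_prev <- mean(cum_at(h, y - 1))
      lam <- (0.03 * ps_prev + 0.21 * p_prev + 0.01) / (1 + (ps_prev / 18)^1.5)
      ll_loop <- ll_loop + dpois(counts[as.character(g), as.character(y)],
                                 lam, log = TRUE)
    }
  }
  expect_equal(log_likelihood(p, h, fit_years = c(1995, 2004)), ll_loop)

  # all-zero counts with k's at the floor: likelihood approaches 0
  h0 <- pub_history(matrix(0L, 3, 4, dimnames = list(1:3, 2001:2004)), 2001:2004)
  p0 <- rate_params(1e-9, 1e-9, 1e-9, 10, 1)
  expect_gt(log_likelihood(p0, h0), -1e-6)
  expect_error(log_likelihood(p, h, fit_years = c(1900, 2004)), "not aligned")
})

test_that("the fitted likelihood never falls below the truth's likelihood", {
  for (s in 1:3) {
    h <- simulate_histories(sim_config(n_genes = 400, year_range = c(1950, 2000),
                                       seed = 500 + s))
    fit <- fit_ml(h, n_starts = 3, seed = s)
    expect_true(fit$convergence)
    expect_gte(fit$loglik + 1e-6, log_likelihood(rate_params(), h))
  }
})

test_that("fitting recovers a null self-momentum component", {
  cfg <- sim_config(n_genes = 3000, year_range = c(1950, 2010),
                    params = rate_params(k1 = 0.05, k2 = 1e-9, k3 = 0.01,
                                         P_S = 24.1, alpha = 1.67),
                    seed = 88)
  h <- simulate_histories(cfg)
  fit <- fit_ml(h, n_starts = 3, seed = 2)
  expect_lt(fit$params["k2"], 0.01)
})

test_that("degenerate all-zero histories drive rates to the bound and get flagged", {
  h0 <- pub_history(matrix(0L, 20, 30, dimnames = list(1:20, 1981:2010)),
                    1981:2010)
  fit <- fit_ml(h0, n_starts = 2, seed = 1)
  expect_lt(fit$params["k3"], 1e-5)
  expect_true(fit$flags["saturation_unidentified"])
})

test_that("Poisson tails are exact against pmf summation and safe in the far tail", {
  expect_equal(poisson_tail(0, 5), 1)
  expect_equal(poisson_tail(5, 2), 1 - exp(-2) * sum(2^(0:4) / factorial(0:4)))
  expect_equal(poisson_tail(5, 2), 0.0526530173, tolerance = 1e-7)
  # far tail: tiny but strictly positive, no underflow to zero
  p40 <- poisson_tail(40, 2)
  expect_gt(p40, 0)
  expect_lt(p40, 1e-30)
  # grid agreement with explicit summation
  set.seed(3)
  for (i in 1:50) {
    mu <- runif(1, 0.01, 30)
    k <- sample(0:100, 1)
    direct <- sum(dpois(k:(k + 400), mu))  # truncated series, error << 1e-12
    expect_lt(abs(poisson_tail(k, mu) - direct), 1e-12)
  }
})

test_that("the hot-gene scan applies the Bonferroni cutoff and flags boosts", {
  # the published-scale denominator: 0.05 / (20,442 * 67)
  expect_equal(0.05 / (20442 * 67), 3.651e-8, tolerance = 1e-3)
  h <- simulate_histories(sim_config(n_genes = 500, year_range = c(1950, 2010),
                                     seed = 42))
  # a steadily-publishing gene boosted ~10x for 3 years
  base_rate <- mean(h$counts[1, as.character(2000:2005)])
  sh <- gwas_shocks(7L, 2003L, boost = 10 * max(base_rate, 3))
  hb <- inject_gwas_shocks(h, sh, seed = 43)
  classes <- tibble::tibble(gene_id = 1:500,
                            first_gwas_year = ifelse(1:500 == 7L, 2003L, NA_integer_))
  scan <- hot_gene_scan(hb, rate_params(), classes = classes)
  expect_equal(scan$cutoff, 0.05 / (500 * 61))
  flagged <- scan$calls[scan$calls$gene_id == 7L, ]
  expect_setequal(flagged$year, 2003:2005)     # all 3 window years flagged
  expect_true(all(flagged$recent_gwas))
  expect_true(all(scan$calls$p < scan$cutoff))
  yr2004 <- scan$summary[scan$summary$year == 2004, ]
  expect_gte(yr2004$n_hot, 1)
  expect_equal(yr2004$n_hot_recent_gwas, sum(flagged$year == 2004))
})

test_that("the hot-gene logistic model recovers signs and detects separation", {
  set.seed(77)
  n <- 6000
  panel <- tibble::tibble(
    log10_recent = runif(n, 0, 2),
    year = sample(1995:2015, n, TRUE),
    recent_gwas = runif(n) < 0.3
  )
  eta <- -6 + 2.5 * panel$log10_recent - 0.05 * (panel$year - 2000) +
    2 * panel$recent_gwas - 0.3 * (panel$year - 2000) * panel$recent_gwas
  panel$significant <- runif(n) < plogis(eta)
  fit <- hot_logistic(panel)
  cf <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- setNames(fit$coefficients$std_error, fit$coefficients$term)
  truth <- c("(Intercept)" = -6, log10_recent = 2.5, year = -0.05,
             recent_gwas = 2, "year:recent_gwas" = -0.3)
  expect_true(all(abs(cf - truth) < 4 * se))
  expect_lt(cf["year:recent_gwas"], 0)

  # no-effect outcome: coefficients compatible with zero
  panel0 <- panel
  set.seed(78)
  panel0$significant <- runif(n) < 0.1
  fit0 <- hot_logistic(panel0)
  z0 <- fit0$coefficients$estimate[-1] / fit0$coefficients$std_error[-1]
  expect_true(all(abs(z0) < 4))

  # constant outcome -> explicit separation error; ridge path still fits
  panel1 <- panel[1:50, ]
  panel1$significant <- TRUE
  expect_error(hot_logistic(panel1), "separation")
  sep <- panel[1:400, ]
  sep$significant <- sep$recent_gwas   # indicator separates perfectly
  expect_error(hot_logistic(sep), "separation|singular")
  ridge_fit <- hot_logistic(sep, penalized = TRUE)
  expect_true(all(is.finite(ridge_fit$coefficients$estimate)))
  expect_gt(ridge_fit$coefficients$estimate[4], 0)
})

test_that("null scans control the family-wise error rate", {
  hits <- vapply(1:60, function(s) {
    h <- simulate_histories(sim_config(n_genes = 400, year_range = c(1971, 2000),
                                       seed = 9000 + s))
    scan <- hot_gene_scan(h, rate_params())
    nrow(scan$calls) > 0
  }, logical(1))
  # Bonferroni at 0.05: <= 5% of null scans show any flag (binomial slack)
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 60))
})
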