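make_history <- function(mat, years, baseline = 0) {
  pub_history(mat, years, baseline)
}

test_that("control matching picks the closest prior history, with depth tie-breaks", {
  years <- 1996:2005
  # gene 1 (gwas): cumulative 10 by 1999; candidates at 8, 11, 13
  counts <- rbind(`1` = c(2, 3, 3, 2, 0, 1, 0, 0, 0, 0),
                  `2` = c(2, 2, 2, 2, 0, 0, 0, 0, 0, 0),
                  `3` = c(3, 3, 3, 2, 0, 0, 1, 0, 0, 0),
                  `4` = c(4, 4, 3, 2, 0, 0, 0, 2, 0, 0))
  colnames(counts) <- years
  h <- make_history(counts, years)
  m <- match_control(1, c(2, 3, 4), h, t0 = 2000)
  expect_s3_class(m, "control_match")
  expect_equal(m$control_ids, 3L)              # cum 11 beats 8 and 13
  expect_equal(m$resolved_depth, 1L)

  # tie at depth 1 resolved by the previous year
  counts2 <- rbind(`1` = c(3, 4, 3),           # cum 1998: 7, cum 1999: 10
                   `2` = c(3, 4, 2),           # cum 1999: 9; cum 1998: 7 (exact)
                   `3` = c(3, 2, 4))           # cum 1999: 9; cum 1998: 5
  colnames(counts2) <- 1997:1999
  h2 <- make_history(counts2, 1997:1999)
  m2 <- match_control(1, c(2, 3), h2, t0 = 2000)
  # both candidates reach 9 by 1999; at 1998 gene 2 matches gene 1 exactly
  expect_equal(m2$control_ids, 2L)
  expect_equal(m2$resolved_depth, 2L)

  # identical full histories -> both returned for downstream averaging
  counts3 <- rbind(`1` = c(1, 2), `2` = c(2, 1), `3` = c(2, 1))
  colnames(counts3) <- 2000:2001
  h3 <- make_history(counts3, 2000:2001)
  m3 <- match_control(1, c(2, 3), h3, t0 = 2002)
  expect_setequal(m3$control_ids, c(2L, 3L))
  expect_error(match_control(1, integer(0), h3, 2002), "empty")
})

test_that("control matching agrees with exhaustive lexicographic search", {
  set.seed(202)
  for (rep in 1:8) {
    n <- 200
    years <- 1990:2009
    counts <- matrix(rpois(n * length(years), 0.8), n,
                     dimnames = list(1:n, years))
    # low-count world forces frequent deep ties
    h <- make_history(counts, years, baseline = rpois(n, 0.5))
    gwas <- sample.int(n, 4)
    cands <- setdiff(1:n, gwas)
    for (g in gwas) {
      t0 <- sample(1995:2007, 1)
      got <- match_control(g, cands, h, t0)
      expect_equal(sort(got$control_ids),
                   match_control_bruteforce(g, cands, h, t0))
    }
  }
})

test_that("raw excess is the window difference against the mean control", {
  counts <- rbind(`1` = c(3, 2, 1), `2` = c(1, 1, 1),
                  `3` = c(0, 0, 0), `4` = c(2, 2, 2))
  colnames(counts) <- 2010:2012
  h <- make_history(counts, 2010:2012)
  expect_equal(publication_excess(h, 1, 2, t0 = 2010, window = 3), 3)
  expect_equal(publication_excess(h, 2, 2, t0 = 2010, window = 3), 0)
  # two controls are averaged: (0+6)/2 = 3 = gene 2's total
  expect_equal(publication_excess(h, 2, c(3, 4), t0 = 2010, window = 3), 0)
  expect_error(publication_excess(h, 1, 2, t0 = 2011, window = 3),
               "not fully covered")
})

test_that("normalization divides by sqrt(recent pubs) with a floor at one", {
  expect_equal(normalize_excess(6, 9), 2)
  expect_equal(normalize_excess(0, 25), 0)
  expect_equal(normalize_excess(3, 0), 3)      # floor: sqrt(max(0,1)) = 1
  expect_error(normalize_excess(1, -2), "recent_pubs >= 0")
})

test_that("the one-sample location test behaves at its edges", {
  expect_error(excess_location_test(rep(0, 10)), "zero variance")
  sym <- rep(c(-1, 1), 25)
  out <- excess_location_test(sym)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  expect_equal(out$mean, 0)
  expect_error(excess_location_test(1), "at least 2")
})

test_that("null worlds give calibrated location tests and ~zero mean excess", {
  ps <- means <- ses <- numeric(40)
  for (s in seq_along(ps)) {
    w <- null_excess_world(n_genes = 250, years = c(1980L, 2012L), n_gwas = 60,
                           t0_range = c(2000L, 2009L), seed = 300 + s)
    rec <- build_excess_records(w$histories, w$classes, w$associations)
    lt <- excess_location_test(rec$norm_excess)
    ps[s] <- lt$p
    means[s] <- lt$mean
    ses[s] <- sd(rec$norm_excess) / sqrt(nrow(rec))
  }
  # mean normalized excess compatible with zero in >= 95% of seeds
  expect_gte(mean(abs(means) < 3 * ses), 0.95)
  # p values roughly uniform under the null
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_gt(mean(ps > 0.05), 0.80)
})

test_that("Spearman correlations detect monotone signal and respect nulls", {
  rec <- tibble::tibble(norm_excess = 1:20,
                        neglog10_p = (1:20)^2,
                        odds_ratio = NA_real_,
                        assoc_date = 2000 + rev(1:20) / 10,
                        log10_recent = rnorm(20))
  out <- predictor_correlations(rec, c("neglog10_p", "assoc_date"))
  expect_equal(out$rho[out$predictor == "neglog10_p"], 1)
  expect_equal(out$rho[out$predictor == "assoc_date"], -1)
  expect_error(predictor_correlations(rec, "odds_ratio"), "fewer than 3")
  set.seed(9)
  null_ps <- replicate(60, {
    r <- tibble::tibble(norm_excess = rnorm(50), x = rnorm(50))
    predictor_correlations(r, "x")$p
  })
  expect_gt(suppressWarnings(ks.test(null_ps, "punif"))$p.value, 0.01)
})

test_that("excess regression recovers planted coefficients and flags collinearity", {
  set.seed(404)
  beta <- c(-0.8, 0.03, 0.1, -0.5)
  covers <- replicate(40, {
    n <- 300
    dat <- tibble::tibble(
      log10_recent = runif(n, 0, 2),
      neglog10_p = runif(n, 5, 30),
      odds_ratio = rlnorm(n, 0.15, 0.2),
      assoc_date = runif(n, 2005, 2015)
    )
    dat$norm_excess <- as.numeric(2 + as.matrix(dat) %*% beta + rnorm(n, sd = 1.5))
    fit <- fit_excess_regression(dat)
    est <- fit$coefficients$estimate[-1]
    se <- fit$coefficients$std_error[-1]
    abs(est - beta) < 1.96 * se + 1e-12    # per-coefficient CI coverage
  })
  expect_gte(mean(covers), 0.90)           # nominal 0.95 over 160 intervals

  bad <- tibble::tibble(norm_excess = rnorm(30), a = rnorm(30), b = 1)
  expect_error(fit_excess_regression(bad, c("a", "b")), "collinear")
})

test_that("robustness filters subset records as configured", {
  rec <- tibble::tibble(neglog10_p = c(6, 9, 12), or_ci_lower = c(1.05, 1.2, NA),
                        norm_excess = 1:3)
  expect_equal(apply_robustness_filters(rec), rec)           # both off
  expect_equal(apply_robustness_filters(rec, p_max = 1e-8)$neglog10_p, c(9, 12))
  expect_equal(apply_robustness_filters(rec, or_ci_min = 1.1)$or_ci_lower, 1.2)
  expect_equal(nrow(apply_robustness_filters(rec, 1e-8, 1.1)), 1L)
})

test_that("the half-year excess series sums records and zero-fills gaps", {
  rec <- tibble::tibble(
    raw_excess = c(5, 3, -1),
    pub_date = as.Date(c("2008-02-10", "2008-09-01", "2009-10-30"))
  )
  ts <- total_excess_timeseries(rec)
  expect_equal(nrow(ts), 4L)  # 2008H1, 2008H2, 2009H1 (empty), 2009H2
  expect_equal(ts$total_raw_excess, c(5, 3, 0, -1))
  expect_equal(ts$n_genes, c(1L, 1L, 0L, 1L))
  one <- total_excess_timeseries(rec[1, ])
  expect_equal(one$total_raw_excess, 5)
})

test_that("a declining GWAS boost shows up as a falling excess series", {
  w <- declining_boost_world(seed = 777, n_gwas = 120)
  rec <- build_excess_records(w$histories, w$classes, w$associations)
  ts <- total_excess_timeseries(rec)
  mid <- stats::median(seq_len(nrow(ts)))
  expect_gt(mean(ts$total_raw_excess[seq_len(floor(mid))]),
            mean(ts$total_raw_excess[-seq_len(floor(mid))]))
})
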