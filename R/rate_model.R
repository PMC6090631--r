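#' Predicted annual publication rate
#'
#' Evaluates the saturating rate model (see [rate_params()]):
#' \deqn{\Delta P = (k_1 P^* + k_2 P_i + k_3) / (1 + (P^*/P_S)^\alpha).}
#' Vectorized over `P_star_t` and `P_it` (recycled together).
#'
#' @param params a [rate_params()] vector
#' @param P_star_t cohort mean cumulative publications \eqn{P^*_t} (>= 0)
#' @param P_it gene cumulative publications \eqn{P_{i,t}} (>= 0)
#' @return expected publications for the following year
#' @export
predict_rate <- function(params, P_star_t, P_it) {
  if (any(P_star_t < 0) || any(P_it < 0)) {
    stop("cumulative publication counts must be non-negative")
  }
  p <- as.numeric(params)
  names(p) <- names(params)
  unname((p["k1"] * P_star_t + p["k2"] * P_it + p["k3"]) /
           (1 + (P_star_t / p["P_S"])^p["alpha"]))
}

# Pre-arrange histories for the likelihood: year-major matrices so per-year
# vectors recycle down columns. Returns X (years x genes), Pprev (lagged
# cumulative), ps (lagged cohort means) over the fit years.
prepare_likelihood_data <- function(histories, cohort = NULL,
                                    fit_years = NULL) {
  stopifnot(inherits(histories, "pub_history"))
  if (is.null(fit_years)) fit_years <- range(histories$years)
  years <- seq.int(fit_years[1], fit_years[2])
  if (!all(years %in% histories$years)) {
    stop("fit years ", fit_years[1], "-", fit_years[2],
         " not aligned with the history span ", histories$years[1], "-",
         histories$years[length(histories$years)])
  }
  if (is.null(cohort)) cohort <- histories
  if (inherits(cohort, "pub_history")) {
    cm <- cohort_means(cohort)
    lag_names <- as.character(years - 1L)
    ps <- ifelse(years - 1L < cohort$years[1], mean(cohort$baseline),
                 cm[lag_names])
    ps <- as.numeric(ps)
  } else {
    # named vector year -> P*_t; must cover fit_years[1]-1 .. fit_years[2]-1
    lag_names <- as.character(years - 1L)
    if (!all(lag_names %in% names(cohort))) {
      stop("cohort means must cover years ", fit_years[1] - 1L, "-",
           fit_years[2] - 1L)
    }
    ps <- as.numeric(cohort[lag_names])
  }
  cumg <- cum_matrix(histories)
  cols <- match(years, histories$years)
  X <- t(histories$counts[, cols, drop = FALSE])
  first_prev <- if (cols[1] == 1L) histories$baseline else cumg[, cols[1] - 1L]
  Pprev <- t(cbind(first_prev, cumg[, cols[-length(cols)], drop = FALSE]))
  dimnames(Pprev) <- dimnames(X)
  list(X = X, Pprev = Pprev, ps = ps, years = years)
}

#' Poisson log-likelihood of the rate model
#'
#' Sum over genes and years of the log Poisson probability of the observed
#' annual count with mean given by the rate model at the previous year's
#' cumulative counts. Means are floored at 1e-10 so boundary parameter
#' values cannot produce `log(0)` against a positive count.
#'
#' @param params a [rate_params()] vector
#' @param histories a [pub_history()] (the genes entering the likelihood)
#' @param cohort the cohort-mean source for \eqn{P^*_t}: a `pub_history`
#'   over the full universe, a named vector `year -> P*`, or NULL to use
#'   `histories` itself
#' @param fit_years first and last year of the likelihood window (default:
#'   the full history span)
#' @return total log-likelihood (a scalar)
#' @export
log_likelihood <- function(params, histories, cohort = NULL,
                           fit_years = NULL) {
  dat <- prepare_likelihood_data(histories, cohort, fit_years)
  lam <- lambda_matrix(as.numeric(params), dat)
  sum(stats::dpois(dat$X, lam, log = TRUE))
}

lambda_matrix <- function(p, dat, floor = 1e-10) {
  S <- (dat$ps / p[4])^p[5]
  lam <- (p[2] * dat$Pprev + (p[1] * dat$ps + p[3])) / (1 + S)
  lam[lam < floor] <- floor
  lam
}

# negative log-likelihood (constant dropped) and gradient in log-parameter
# space; closure over prepared data for speed inside optim
make_nll <- function(dat, floor = 1e-10) {
  X <- dat$X; ps <- dat$ps; Pprev <- dat$Pprev
  lpos <- ifelse(ps > 0, log(ps), 0)
  function(theta, gradient = FALSE) {
    p <- exp(theta)
    S <- (ps / p[4])^p[5]
    D <- 1 + S
    lam <- (p[2] * Pprev + (p[1] * ps + p[3])) / D
    lam[lam < floor] <- floor
    if (!gradient) return(-sum(X * log(lam) - lam))
    W <- X / lam - 1
    rs <- rowSums(W)
    t1 <- rowSums(W * lam)
    lr <- ifelse(ps > 0, lpos - log(p[4]), 0)
    g <- c(sum(rs * ps / D),
           sum(rowSums(W * Pprev) / D),
           sum(rs / D),
           p[5] / p[4] * sum(t1 * S / D),
           -sum(t1 * S * lr / D))
    -g * p
  }
}

#' Maximum-likelihood fit of the rate model
#'
#' Maximizes the Poisson likelihood over the five parameters by bounded
#' quasi-Newton (L-BFGS-B) search in log-parameter space with analytic
#' gradients, from several starting points (one heuristic start plus
#' log-uniform random restarts), keeping the best converged solution.
#'
#' @param histories a [pub_history()] of the genes to fit (typically the
#'   never-GWAS genes)
#' @param cohort cohort-mean source for \eqn{P^*_t}, as in
#'   [log_likelihood()]; pass the full-universe histories when fitting on a
#'   subset
#' @param fit_years likelihood window, default the full history span
#'   (1950-2015 at the published analysis scale)
#' @param n_starts number of optimization starts (default 5)
#' @param seed RNG seed for the random starts
#' @param init optional numeric length-5 starting value for the first start
#' @param bounds lower/upper parameter bounds, default `c(1e-6, 1e3)`
#' @return list of class `rate_fit`: `params` ([rate_params()]), `loglik`
#'   (full log-likelihood including constants), `convergence` (TRUE if any
#'   start converged), `starts` (per-start tibble), `fit_years`, `flags`
#'   (named logicals: `at_bounds`, `saturation_unidentified`)
#' @export
fit_ml <- function(histories, cohort = NULL, fit_years = NULL,
                   n_starts = 5L, seed = 1L, init = NULL,
                   bounds = c(1e-6, 1e3)) {
  if (is.null(fit_years)) fit_years <- range(histories$years)
  dat <- prepare_likelihood_data(histories, cohort, fit_years)
  if (nrow(dat$X) < 2L || ncol(dat$X) < 2L) {
    stop("need at least 2 genes and 2 years to fit")
  }
  nll <- make_nll(dat)
  fn <- function(th) nll(th, gradient = FALSE)
  gr <- function(th) nll(th, gradient = TRUE)
  set.seed(seed)
  starts <- vector("list", n_starts)
  if (is.null(init)) {
    init <- c(k1 = 0.01, k2 = 0.1,
              k3 = max(mean(dat$X[1, ]), 1e-3),
              P_S = max(stats::median(dat$ps), 1),
              alpha = 1)
  }
  starts[[1]] <- log(pmin(pmax(as.numeric(init), bounds[1]), bounds[2]))
  for (s in seq_len(n_starts)[-1]) {
    starts[[s]] <- log(c(10^stats::runif(3, -4, 0),
                         10^stats::runif(1, 0, 3),
                         10^stats::runif(1, -0.7, 0.7)))
  }
  runs <- lapply(seq_len(n_starts), function(s) {
    res <- tryCatch(
      stats::optim(starts[[s]], fn, gr, method = "L-BFGS-B",
                   lower = log(bounds[1]), upper = log(bounds[2]),
                   control = list(maxit = 500L)),
      error = function(e) list(par = starts[[s]], value = Inf,
                               convergence = 99L, message = conditionMessage(e))
    )
    tibble::tibble(start = s, nll = res$value,
                   converged = identical(res$convergence, 0L),
                   par = list(exp(res$par)))
  })
  runs <- dplyr::bind_rows(runs)
  ok <- runs[runs$converged & is.finite(runs$nll), , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop("rate-model fit failed to converge from any of ", n_starts,
         " starts; best objective ", format(min(runs$nll)))
  }
  best <- ok$par[[which.min(ok$nll)]]
  params <- rate_params(best[1], best[2], best[3], best[4], best[5])
  at_lo <- abs(log(as.numeric(params)) - log(bounds[1])) < 1e-6
  at_hi <- abs(log(as.numeric(params)) - log(bounds[2])) < 1e-6
  flags <- c(at_bounds = any(at_lo | at_hi),
             saturation_unidentified = sum(dat$X) == 0 ||
               any((at_lo | at_hi)[4:5]))
  ll <- -min(ok$nll) - sum(lfactorial(dat$X))
  structure(list(params = params, loglik = ll,
                 convergence = TRUE, starts = runs,
                 fit_years = fit_years, flags = flags),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> years %d-%d, logLik = %.1f%s\n",
              x$fit_years[1], x$fit_years[2], x$loglik,
              if (x$flags["at_bounds"]) " [parameters at bounds]" else ""))
  print(round(unclass(x$params), 5))
  invisible(x)
}

#' Upper-tail Poisson probability
#'
#' `P(X >= observed)` for `X ~ Poisson(mean)`, computed through the
#' survival function of the Poisson distribution (regularized incomplete
#' gamma machinery), so extreme tails retain full floating-point precision
#' rather than underflowing through `1 - CDF`. Vectorized.
#'
#' @param observed non-negative integer count(s)
#' @param mean positive Poisson mean(s)
#' @return tail probability in (0, 1]
#' @export
poisson_tail <- function(observed, mean) {
  stopifnot(all(observed >= 0), all(mean > 0))
  stats::ppois(observed - 1, lambda = mean, lower.tail = FALSE)
}

#' Scan for exceptionally studied gene-years
#'
#' Compares every gene-year's observed publication count with the rate
#' model's expectation given the gene's history, flagging gene-years whose
#' one-sided Poisson tail probability falls below the Bonferroni-corrected
#' cutoff `alpha / (N_g * N_y)`. When class labels are supplied, each call
#' also records whether the gene was newly GWAS-associated within the past
#' 3 years (the panel year and the two before it), and annual summaries
#' count hot genes, hot-and-recent-GWAS genes and new GWAS genes.
#'
#' @param histories full-universe [pub_history()]
#' @param params fitted [rate_params()] (trained on never-GWAS genes)
#' @param cohort cohort-mean source, as in [log_likelihood()]
#' @param scan_years years to scan (default: all history years)
#' @param N_g,N_y Bonferroni denominators; default to the number of genes
#'   in the universe and the number of scanned years
#' @param classes optional tibble with `gene_id`, `first_gwas_year`
#' @param alpha family-wise error target, default 0.05
#' @param keep_panel if TRUE, return the full gene-year panel (for the
#'   hot-gene logistic model), else only the significant calls
#' @return list `calls` (significant gene-years: `gene_id`, `year`,
#'   `observed`, `expected`, `p`, `significant`, `recent_gwas`), `summary`
#'   (annual counts), `cutoff`, and `panel` when requested
#' @export
hot_gene_scan <- function(histories, params, cohort = NULL, scan_years = NULL,
                          N_g = NULL, N_y = NULL, classes = NULL,
                          alpha = 0.05, keep_panel = FALSE) {
  if (is.null(scan_years)) scan_years <- histories$years
  dat <- prepare_likelihood_data(histories, cohort,
                                 c(scan_years[1], scan_years[length(scan_years)]))
  if (is.null(N_g)) N_g <- nrow(histories$counts)
  if (is.null(N_y)) N_y <- length(dat$years)
  cutoff <- alpha / (N_g * N_y)
  lam <- lambda_matrix(as.numeric(params), dat)
  p <- poisson_tail(dat$X, lam)
  sig <- p < cutoff

  first_year <- NULL
  if (!is.null(classes)) {
    first_year <- classes$first_gwas_year[match(as.integer(colnames(dat$X)),
                                                classes$gene_id)]
  }
  panel_rows <- function(idx) {
    yr <- dat$years[row(dat$X)[idx]]
    gid <- as.integer(colnames(dat$X)[col(dat$X)[idx]])
    fg <- if (is.null(first_year)) rep(NA_integer_, length(idx)) else
      first_year[col(dat$X)[idx]]
    tibble::tibble(
      gene_id = gid, year = yr,
      observed = as.integer(dat$X[idx]), expected = lam[idx],
      p = p[idx], significant = sig[idx],
      recent_gwas = !is.na(fg) & fg >= yr - 2L & fg <= yr
    )
  }
  calls <- panel_rows(which(sig))
  calls <- dplyr::arrange(calls, .data$year, .data$gene_id)

  recent_mat <- if (is.null(first_year)) {
    matrix(FALSE, nrow(dat$X), ncol(dat$X))
  } else {
    outer(dat$years, first_year, function(y, f) !is.na(f) & f >= y - 2L & f <= y)
  }
  summary <- tibble::tibble(
    year = dat$years,
    n_hot = unname(rowSums(sig)),
    n_hot_recent_gwas = unname(rowSums(sig & recent_mat)),
    n_new_gwas = if (is.null(first_year)) NA_integer_ else
      vapply(dat$years, function(y) sum(first_year == y, na.rm = TRUE), integer(1))
  )
  summary$prop_hot_recent <- ifelse(summary$n_hot > 0,
                                    summary$n_hot_recent_gwas / summary$n_hot, NA)
  out <- list(calls = calls, summary = summary, cutoff = cutoff,
              N_g = N_g, N_y = N_y)
  if (keep_panel) {
    panel <- panel_rows(seq_along(dat$X))
    # recent pubs: the 3 calendar years strictly before the panel year
    recent <- t(vapply(dat$years, function(y) {
      cum_at(histories, y - 1L) - cum_at(histories, y - 4L)
    }, numeric(nrow(histories$counts))))  # years x genes
    panel$recent_pubs <- as.integer(recent[seq_along(dat$X)])
    panel$log10_recent <- log10(pmax(panel$recent_pubs, 1))
    out$panel <- panel
  }
  out
}

#' Logistic model for hot gene-years
#'
#' Fits, by maximum likelihood, the probability that a gene-year is hot
#' (Bonferroni-significant publication excess) on log10(recent
#' publications), calendar year, a recent-GWAS indicator, and the
#' year-by-recent-GWAS interaction. Year is centered (default at 2000) for
#' numerical stability; the interaction's sign is unaffected. On perfect
#' or quasi-perfect separation the unpenalized fit stops with an error
#' advising the ridge-stabilized alternative (`penalized = TRUE`), which
#' adds a small L2 penalty to the Newton iterations and reports standard
#' errors from the penalized information matrix.
#'
#' @param panel tibble with `significant`, `log10_recent`, `year`,
#'   `recent_gwas` (from [hot_gene_scan()] with `keep_panel = TRUE`)
#' @param penalized use the ridge-stabilized fit
#' @param ridge L2 penalty for the stabilized fit
#' @param year_center year subtracted before fitting
#' @return list of class `hot_fit`: `coefficients` (tibble `term`,
#'   `estimate`, `std_error`, `p_value`), `n`, `penalized`
#' @export
hot_logistic <- function(panel, penalized = FALSE, ridge = 1e-2,
                         year_center = 2000) {
  y <- as.integer(panel$significant)
  if (all(y == 1L) || all(y == 0L)) {
    stop("outcome is constant (all ", if (all(y == 1L)) "hot" else "cold",
         "); perfect separation - no logistic fit is possible")
  }
  X <- cbind(`(Intercept)` = 1,
             log10_recent = panel$log10_recent,
             year = panel$year - year_center,
             recent_gwas = as.numeric(panel$recent_gwas))
  X <- cbind(X, `year:recent_gwas` = X[, "year"] * X[, "recent_gwas"])
  if (!penalized) {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial())
    )
    mu <- fit$fitted.values
    separated <- !fit$converged || any(abs(fit$coefficients) > 20) ||
      all(mu[y == 1L] > 1 - 1e-8) || all(mu[y == 0L] < 1e-8)
    if (separated) {
      stop("(quasi-)separation detected in the hot-gene logistic model; ",
           "refit with penalized = TRUE for a ridge-stabilized fit")
    }
    w <- mu * (1 - mu)
    info <- crossprod(X * sqrt(w))
    se <- sqrt(diag(solve(info)))
    beta <- fit$coefficients
  } else {
    beta <- rep(0, ncol(X))
    pen <- diag(ridge, ncol(X)); pen[1, 1] <- 0  # intercept unpenalized
    for (it in 1:100) {
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      H <- crossprod(X * sqrt(w)) + pen
      score <- crossprod(X, y - mu) - pen %*% beta
      step <- solve(H, score)
      beta <- beta + step
      if (max(abs(step)) < 1e-8) break
    }
    se <- sqrt(diag(solve(H)))
  }
  z <- beta / se
  coefs <- tibble::tibble(
    term = colnames(X), estimate = as.numeric(beta),
    std_error = as.numeric(se),
    p_value = 2 * stats::pnorm(-abs(as.numeric(z)))
  )
  structure(list(coefficients = coefs, n = length(y), penalized = penalized),
            class = "hot_fit")
}

#' @export
print.hot_fit <- function(x, ...) {
  cat(sprintf("<hot_fit> n = %d gene-years%s\n", x$n,
              if (x$penalized) " (ridge-stabilized)" else ""))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}
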