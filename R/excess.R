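#' Match a newly associated gene to control gene(s)
#'
#' The control for a GWAS gene first associated in year `t0` is the
#' never-GWAS gene whose total publications prior to `t0` are closest to
#' the GWAS gene's. Ties are resolved by comparing cumulative totals one
#' year earlier, then another year earlier, and so on back to the first
#' year of the histories; genes still tied after that are all returned and
#' averaged downstream.
#'
#' @param gwas_gene integer id of the newly associated gene
#' @param candidates integer ids of genes never GWAS-associated
#' @param histories a [pub_history()] covering gene and candidates
#' @param t0 first association year
#' @param cum precomputed [cum_matrix()] of `histories` (optional, for
#'   repeated calls)
#' @return list of class `control_match`: `gwas_gene_id`, `control_ids`
#'   (one or more), `match_year` (= t0), `resolved_depth` (years compared)
#' @export
match_control <- function(gwas_gene, candidates, histories, t0, cum = NULL) {
  if (length(candidates) == 0L) stop("empty control candidate pool")
  if (is.null(cum)) cum <- cum_matrix(histories)
  years <- histories$years
  g <- as.character(gwas_gene)
  cand <- as.character(candidates)
  depth <- 0L
  tied <- cand
  compare_years <- if (t0 - 1L >= years[1]) seq.int(t0 - 1L, years[1]) else years[1] - 1L
  for (y in compare_years) {
    depth <- depth + 1L
    cg <- if (y < years[1]) histories$baseline[g] else cum[g, as.character(y)]
    cc <- if (y < years[1]) histories$baseline[tied] else cum[tied, as.character(y)]
    d <- abs(cc - cg)
    tied <- tied[d == min(d)]
    if (length(tied) == 1L) break
  }
  structure(list(gwas_gene_id = as.integer(gwas_gene),
                 control_ids = as.integer(tied),
                 match_year = as.integer(t0),
                 resolved_depth = depth),
            class = "control_match")
}

#' Raw publication excess over the follow-up window
#'
#' Publications on the GWAS gene during the association year and the
#' following `window - 1` years, minus the mean of the same sum over its
#' control gene(s).
#'
#' @param histories a [pub_history()]
#' @param gene_id GWAS gene id
#' @param control_ids one or more control gene ids
#' @param t0 association year
#' @param window window length in years (default 3)
#' @return numeric raw excess
#' @export
publication_excess <- function(histories, gene_id, control_ids, t0, window = 3L) {
  last <- histories$years[length(histories$years)]
  if (t0 + window - 1L > last || t0 < histories$years[1]) {
    stop("follow-up window ", t0, "-", t0 + window - 1L,
         " not fully covered by the histories")
  }
  w <- window_counts(histories, t0, t0 + window - 1L)
  unname(w[as.character(gene_id)] - mean(w[as.character(control_ids)]))
}

#' Variance-stabilized publication excess
#'
#' Divides the raw excess by the square root of the gene's recent
#' publication count, flooring the denominator at one so the statistic is
#' defined (and equals the raw excess) for previously unstudied genes.
#' Under a Poisson publication model this square-root scaling equalizes the
#' variance across genes of different prior activity.
#'
#' @param raw_excess numeric raw excess
#' @param recent_pubs publications on the gene in the 3 years before `t0`
#' @return normalized excess
#' @export
normalize_excess <- function(raw_excess, recent_pubs) {
  stopifnot(all(recent_pubs >= 0))
  raw_excess / sqrt(pmax(recent_pubs, 1))
}

#' Build excess records for all newly associated genes
#'
#' For every gene with a first GWAS association year such that the full
#' follow-up window fits in the histories, finds the matched control(s),
#' computes raw and normalized excess, and assembles the regression
#' predictors. `recent_pubs` counts the 3 calendar years strictly before
#' `t0` (`t0-3 .. t0-1`), keeping the predictor clear of the outcome
#' window. The association date enters as a decimal year (month precision
#' when the catalog carries it, else mid-year).
#'
#' @param histories a [pub_history()] over the full universe
#' @param classes tibble from [classify_genes()] (supplies
#'   `first_gwas_year`, `first_assoc_p`, `first_assoc_or`)
#' @param associations association tibble (supplies dates and CI bounds)
#' @param window follow-up window in years, default 3 (5 for the
#'   longer-horizon robustness variant)
#' @param recent_window years of the recent-publication predictor, default 3
#' @return tibble of excess records, one row per eligible GWAS gene:
#'   `gwas_gene_id`, `t0`, `window`, `control_ids` (list), `n_controls`,
#'   `resolved_depth`, `raw_excess`, `recent_pubs`, `norm_excess`,
#'   `log10_recent`, `neglog10_p`, `odds_ratio`, `or_ci_lower`,
#'   `assoc_date`, `pub_date`, `trait_class`
#' @export
build_excess_records <- function(histories, classes, associations,
                                 window = 3L, recent_window = 3L) {
  gwas <- classes[!is.na(classes$first_gwas_year), , drop = FALSE]
  last <- histories$years[length(histories$years)]
  eligible <- gwas$first_gwas_year + window - 1L <= last
  gwas <- gwas[eligible, , drop = FALSE]
  if (nrow(gwas) == 0L) stop("no GWAS gene has a complete follow-up window")
  candidates <- setdiff(classes$gene_id[is.na(classes$first_gwas_year)],
                        gwas$gene_id)
  cum <- cum_matrix(histories)

  # earliest association row per gene, for date / trait / CI details
  assoc_first <- dplyr::slice_min(dplyr::group_by(associations, .data$gene_id),
                                  order_by = .data$pub_date, n = 1L,
                                  with_ties = FALSE)
  assoc_first <- dplyr::ungroup(assoc_first)

  rows <- vector("list", nrow(gwas))
  for (i in seq_len(nrow(gwas))) {
    g <- gwas$gene_id[i]
    t0 <- gwas$first_gwas_year[i]
    m <- match_control(g, candidates, histories, t0, cum = cum)
    raw <- publication_excess(histories, g, m$control_ids, t0, window)
    recent <- sum(window_counts(subset_genes(histories, g),
                                t0 - recent_window, t0 - 1L))
    ar <- assoc_first[assoc_first$gene_id == g, , drop = FALSE]
    pub_date <- if (nrow(ar)) ar$pub_date[1] else as.Date(sprintf("%d-07-01", t0))
    rows[[i]] <- tibble::tibble(
      gwas_gene_id = g, t0 = t0, window = as.integer(window),
      control_ids = list(m$control_ids), n_controls = length(m$control_ids),
      resolved_depth = m$resolved_depth,
      raw_excess = raw, recent_pubs = recent,
      norm_excess = normalize_excess(raw, recent),
      log10_recent = log10(pmax(recent, 1)),
      neglog10_p = -log10(gwas$first_assoc_p[i]),
      odds_ratio = gwas$first_assoc_or[i],
      or_ci_lower = if (nrow(ar)) ar$or_ci_lower[1] else NA_real_,
      assoc_date = decimal_year(pub_date),
      pub_date = pub_date,
      trait_class = if (nrow(ar) && "trait_id" %in% names(ar)) ar$trait_id[1] else NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

decimal_year <- function(date) {
  y <- as.integer(format(date, "%Y"))
  start <- as.Date(sprintf("%d-01-01", y))
  len <- ifelse(format(date, "%m-%d") >= "02-29" &
                  (y %% 4 == 0 & (y %% 100 != 0 | y %% 400 == 0)), 366, 365)
  y + as.numeric(date - start) / len
}

#' One-sample location test of the normalized excess
#'
#' Two-sided one-sample t test of the normalized publication excess against
#' zero: does GWAS association shift subsequent publications at all?
#'
#' @param norm_excesses numeric vector of normalized excesses
#' @return list `t`, `p`, `mean`, `n`
#' @export
excess_location_test <- function(norm_excesses) {
  norm_excesses <- norm_excesses[!is.na(norm_excesses)]
  if (length(norm_excesses) < 2L) stop("need at least 2 excess values")
  if (stats::sd(norm_excesses) == 0) {
    stop("zero variance in normalized excess; t test degenerate")
  }
  tt <- stats::t.test(norm_excesses, mu = 0, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       mean = mean(norm_excesses), n = length(norm_excesses))
}

#' Spearman correlations of the normalized excess with its predictors
#'
#' Rank correlation (tie-corrected, asymptotic p) of the normalized excess
#' with each predictor, on the records where that predictor is non-missing.
#'
#' @param records tibble from [build_excess_records()]
#' @param predictors columns to correlate, default the four of the headline
#'   model
#' @return tibble `predictor`, `rho`, `p`, `n`
#' @export
predictor_correlations <- function(records,
                                   predictors = c("neglog10_p", "odds_ratio",
                                                  "assoc_date", "log10_recent")) {
  out <- lapply(predictors, function(v) {
    ok <- !is.na(records[[v]]) & !is.na(records$norm_excess)
    if (sum(ok) < 3L) stop("fewer than 3 complete pairs for predictor ", v)
    ct <- suppressWarnings(
      stats::cor.test(records[[v]][ok], records$norm_excess[ok],
                      method = "spearman", exact = FALSE)
    )
    tibble::tibble(predictor = v, rho = unname(ct$estimate),
                   p = ct$p.value, n = sum(ok))
  })
  dplyr::bind_rows(out)
}

#' Linear regression model for the normalized excess
#'
#' Ordinary least squares of the normalized publication excess on
#' log10(recent publications), -log10(association p), the estimated odds
#' ratio, and the association date (decimal year), on complete cases.
#' Additional covariates (e.g. trait-class indicators) may be appended.
#'
#' @param records tibble from [build_excess_records()]
#' @param covariates character vector of predictor columns
#' @return list of class `excess_fit`: `coefficients` (tibble `term`,
#'   `estimate`, `std_error`, `p_value`), `n`, `r_squared`, `model` (the
#'   `lm` fit)
#' @export
fit_excess_regression <- function(records,
                                  covariates = c("log10_recent", "neglog10_p",
                                                 "odds_ratio", "assoc_date")) {
  dat <- records[, c("norm_excess", covariates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) <= length(covariates) + 1L) {
    stop("too few complete cases (", nrow(dat), ") for the regression")
  }
  fml <- stats::as.formula(paste("norm_excess ~", paste(covariates, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    std_error = sm$coefficients[, 2],
    p_value = sm$coefficients[, 4]
  )
  structure(list(coefficients = coefs, n = nrow(dat),
                 r_squared = sm$r.squared, model = fit),
            class = "excess_fit")
}

#' @export
print.excess_fit <- function(x, ...) {
  cat(sprintf("<excess_fit> n = %d, R^2 = %.3f\n", x$n, x$r_squared))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Restrict records to high-confidence associations
#'
#' Optional robustness filters: keep only genes whose first association has
#' `p < p_max` (e.g. 1e-8, the conventional threshold for low-frequency
#' variants), and/or whose odds-ratio 95% CI lower bound exceeds
#' `or_ci_min` (e.g. 1.1). Both filters are off (`NULL`) by default.
#'
#' @param records tibble from [build_excess_records()]
#' @param p_max upper bound on the association p-value, or NULL
#' @param or_ci_min lower bound on the OR CI lower limit, or NULL
#' @return filtered records
#' @export
apply_robustness_filters <- function(records, p_max = NULL, or_ci_min = NULL) {
  if (!is.null(p_max)) {
    records <- records[!is.na(records$neglog10_p) &
                         records$neglog10_p > -log10(p_max), , drop = FALSE]
  }
  if (!is.null(or_ci_min)) {
    records <- records[!is.na(records$or_ci_lower) &
                         records$or_ci_lower > or_ci_min, , drop = FALSE]
  }
  records
}

#' Total publication excess over calendar half-years
#'
#' Sums the raw publication excess of genes newly associated during each
#' `bin_months`-month period of their association date. Periods between the
#' first and last association with no new genes appear with total 0.
#'
#' @param records tibble from [build_excess_records()] (uses `pub_date`)
#' @param bin_months bin width in months; must divide 12 (default 6)
#' @return tibble `bin_start` (Date), `total_raw_excess`, `n_genes`
#' @export
total_excess_timeseries <- function(records, bin_months = 6L) {
  stopifnot(12L %% bin_months == 0L)
  if (nrow(records) == 0L) {
    return(tibble::tibble(bin_start = as.Date(character()),
                          total_raw_excess = numeric(), n_genes = integer()))
  }
  y <- as.integer(format(records$pub_date, "%Y"))
  m <- as.integer(format(records$pub_date, "%m"))
  bin_m <- ((m - 1L) %/% bin_months) * bin_months + 1L
  bin_start <- as.Date(sprintf("%04d-%02d-01", y, bin_m))
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin_start, x = records$raw_excess), .data$bin_start),
    total_raw_excess = sum(.data$x), n_genes = dplyr::n(), .groups = "drop"
  )
  all_bins <- seq(min(bin_start), max(bin_start), by = paste(bin_months, "months"))
  out <- dplyr::left_join(tibble::tibble(bin_start = all_bins), agg, by = "bin_start")
  out$total_raw_excess[is.na(out$total_raw_excess)] <- 0
  out$n_genes[is.na(out$n_genes)] <- 0L
  out
}
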