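#' Configuration for an end-to-end run
#'
#' Exactly one input mode is active: `"simulate"` (a [sim_config()] plus a
#' shock schedule, no files needed) or `"ingest"` (paths to the six input
#' files). The remaining fields control the downstream analyses.
#'
#' @param mode `"simulate"` or `"ingest"`
#' @param sim a [sim_config()] (simulate mode)
#' @param shocks a [gwas_shocks()] tibble (simulate mode; may be empty)
#' @param paths named list of input paths (ingest mode): `gene2pubmed`,
#'   `years`, `omim`, `gwas`, `efo_terms`, `genes`
#' @param era_cutoff pre/post era boundary year
#' @param window follow-up window (3 or 5)
#' @param p_max,or_ci_min robustness filters (NULL = off)
#' @param seed root seed; every stochastic stage derives its seed from it
#' @param out_dir run output directory
#' @return list of class `run_config`
#' @export
run_config <- function(mode = c("simulate", "ingest"), sim = NULL,
                       shocks = NULL, paths = NULL, era_cutoff = 2005L,
                       window = 3L, p_max = NULL, or_ci_min = NULL,
                       seed = 1L, out_dir = tempfile("pubpulse_run")) {
  mode <- match.arg(mode)
  if (mode == "simulate") {
    if (is.null(sim)) sim <- sim_config(seed = seed)
    if (!is.null(paths)) stop("simulate mode takes no input paths")
    if (is.null(shocks)) shocks <- gwas_shocks(integer(0), integer(0), numeric(0))
  } else {
    need <- c("gene2pubmed", "years", "omim", "gwas", "efo_terms", "genes")
    if (is.null(paths) || !all(need %in% names(paths))) {
      stop("ingest mode needs paths: ", paste(need, collapse = ", "))
    }
    missing <- need[!vapply(paths[need], file.exists, logical(1))]
    if (length(missing)) {
      stop("missing input file(s): ",
           paste(sprintf("%s (%s)", missing, unlist(paths[missing])), collapse = ", "))
    }
    if (!is.null(sim)) stop("ingest mode takes no simulation config")
  }
  structure(list(mode = mode, sim = sim, shocks = shocks, paths = paths,
                 era_cutoff = as.integer(era_cutoff), window = as.integer(window),
                 p_max = p_max, or_ci_min = or_ci_min, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order -- simulate (or read inputs),
#' ingest, inequality analysis, matched-control excess analysis, rate-model
#' fit and hot-gene scan -- writing every stage output as plain TSV/JSON
#' under the run directory, plus `manifest.json` recording the package
#' version, seeds, filter accounting and an md5 checksum of every output
#' file. Deterministic stages are bit-identical across reruns with the
#' same config.
#'
#' @param config a [run_config()]
#' @return invisible path of the run directory
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  accounting <- list()

  if (config$mode == "simulate") {
    world <- stage("simulate", {
      h <- simulate_histories(config$sim)
      h <- inject_gwas_shocks(h, config$shocks, seed = config$seed + 1L)
      gi <- synthetic_gene_info(as.integer(rownames(h$counts)))
      catalog <- generate_association_table(config$shocks, gi,
                                            seed = config$seed + 2L)
      omim <- tibble::tibble(gene_id = integer(0), trait_kind = character(0))
      bundle_dir <- file.path(config$out_dir, "bundle")
      paths <- write_fixture_bundle(h, omim, catalog, bundle_dir, gene_info = gi)
      as.list(paths)
    })
  } else {
    world <- config$paths
  }

  ing <- stage("ingest", do.call(ingest_bundle, c(
    world[c("gene2pubmed", "years", "omim", "gwas", "efo_terms", "genes")],
    list(year_range = if (config$mode == "simulate") config$sim$year_range
         else c(1950L, 2015L))
  )))
  accounting$ingest <- as.list(ing$accounting)

  ineq <- stage("inequality", {
    es <- era_split(ing$histories, config$era_cutoff)
    total <- es$pre + es$post
    rd <- rank_distribution(stats::setNames(total, es$gene_id), ing$classes)
    ginis <- list(
      total = gini(total),
      pre = if (sum(es$pre) > 0) gini(es$pre) else NA_real_,
      post = if (sum(es$post) > 0) gini(es$post) else NA_real_
    )
    shift <- if (sum(!is.na(ing$classes$first_gwas_year)) >= 2) {
      tryCatch(rank_shift_test(stats::setNames(es$pre, es$gene_id),
                               stats::setNames(es$post, es$gene_id),
                               ing$classes)[c("U", "p", "n")],
               error = function(e) NULL)
    }
    list(era = es, ranks = rd, ginis = ginis, shift = shift)
  })

  exc <- stage("excess", {
    if (all(is.na(ing$classes$first_gwas_year))) {
      NULL
    } else {
      rec <- build_excess_records(ing$histories, ing$classes, ing$associations,
                                  window = config$window)
      rec <- apply_robustness_filters(rec, config$p_max, config$or_ci_min)
      loc <- tryCatch(excess_location_test(rec$norm_excess), error = function(e) NULL)
      cors <- tryCatch(predictor_correlations(rec), error = function(e) NULL)
      reg <- tryCatch(fit_excess_regression(rec), error = function(e) NULL)
      ts <- total_excess_timeseries(rec)
      list(records = rec, location = loc, correlations = cors,
           regression = reg, timeseries = ts)
    }
  })

  rm_out <- stage("rate_model", {
    non_gwas <- ing$classes$gene_id[is.na(ing$classes$first_gwas_year)]
    fit <- fit_ml(subset_genes(ing$histories, non_gwas), cohort = ing$histories,
                  fit_years = range(ing$histories$years),
                  seed = config$seed + 3L)
    scan <- hot_gene_scan(ing$histories, fit$params, cohort = ing$histories,
                          classes = ing$classes)
    list(fit = fit, scan = scan)
  })

  # ---- write stage outputs -------------------------------------------------
  o <- function(...) file.path(config$out_dir, ...)
  readr::write_tsv(dplyr::left_join(ineq$era,
                                    dplyr::select(ineq$ranks, "gene_id", "rank", "label"),
                                    by = "gene_id"),
                   o("inequality_per_gene.tsv"), progress = FALSE)
  jsonlite::write_json(c(ineq$ginis, list(rank_shift = ineq$shift)),
                       o("inequality_gini.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(exc)) {
    rec_flat <- exc$records
    rec_flat$control_ids <- vapply(rec_flat$control_ids, paste, character(1),
                                   collapse = ",")
    readr::write_tsv(rec_flat, o("excess_records.tsv"), progress = FALSE)
    if (!is.null(exc$correlations)) {
      jsonlite::write_json(list(location = exc$location,
                                correlations = exc$correlations),
                           o("excess_stats.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    if (!is.null(exc$regression)) {
      readr::write_tsv(exc$regression$coefficients,
                       o("excess_regression.tsv"), progress = FALSE)
    }
    readr::write_tsv(exc$timeseries, o("excess_timeseries.tsv"), progress = FALSE)
  }
  jsonlite::write_json(list(params = as.list(unclass(rm_out$fit$params)),
                            loglik = rm_out$fit$loglik,
                            fit_years = rm_out$fit$fit_years,
                            convergence = rm_out$fit$convergence,
                            flags = as.list(rm_out$fit$flags)),
                       o("rate_model_params.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  readr::write_tsv(rm_out$scan$calls, o("hot_gene_calls.tsv"), progress = FALSE)
  readr::write_tsv(rm_out$scan$summary, o("hot_gene_summary.tsv"), progress = FALSE)

  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    package = "pubpulse",
    version = as.character(utils::packageVersion("pubpulse")),
    mode = config$mode,
    seed = config$seed,
    era_cutoff = config$era_cutoff,
    window = config$window,
    filters = list(p_max = config$p_max, or_ci_min = config$or_ci_min),
    accounting = accounting,
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(o(f))), bytes = file.size(o(f)))
    })
  )
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Summarize a completed run
#'
#' One-page markdown summary of a run directory: Gini coefficients by era,
#' the mean normalized excess with its t test, the regression coefficient
#' table, and annual hot-gene counts. Incomplete runs yield a partial
#' report with warnings.
#'
#' @param run_dir directory written by [run_pipeline()]
#' @return character vector of report lines (invisibly written to
#'   `report.md` in the run directory)
#' @export
report <- function(run_dir) {
  o <- function(...) file.path(run_dir, ...)
  lines <- c("# pubpulse run report", "")
  if (file.exists(o("manifest.json"))) {
    man <- jsonlite::read_json(o("manifest.json"))
    lines <- c(lines, sprintf("Mode: %s; seed %s; era cutoff %s; window %s years.",
                              man$mode, man$seed, man$era_cutoff, man$window), "")
  } else {
    warning("no manifest.json; incomplete run")
  }
  if (file.exists(o("inequality_gini.json"))) {
    g <- jsonlite::read_json(o("inequality_gini.json"))
    fmt_g <- function(x) if (is.null(x) || is.na(x)) "NA" else sprintf("%.3f", x)
    lines <- c(lines, "## Publication inequality",
               sprintf("Gini coefficient: total %s, pre-era %s, post-era %s.",
                       fmt_g(g$total), fmt_g(g$pre), fmt_g(g$post)))
    if (!is.null(g$rank_shift)) {
      lines <- c(lines, sprintf("Rank-shift Mann-Whitney: U = %s, p = %.3g (n = %s).",
                                format(g$rank_shift$U), g$rank_shift$p,
                                g$rank_shift$n))
    }
    lines <- c(lines, "")
  } else warning("inequality outputs missing")
  if (file.exists(o("excess_stats.json"))) {
    s <- jsonlite::read_json(o("excess_stats.json"))
    lines <- c(lines, "## Matched-control publication excess",
               sprintf("Mean normalized excess %.3f (t = %.2f, p = %.3g, n = %d).",
                       s$location$mean, s$location$t, s$location$p, s$location$n))
    if (file.exists(o("excess_regression.tsv"))) {
      reg <- readr::read_tsv(o("excess_regression.tsv"),
                             col_types = "cddd", progress = FALSE)
      lines <- c(lines, "", "Regression of normalized excess:",
                 utils::capture.output(print(as.data.frame(reg), digits = 3)))
    }
    lines <- c(lines, "")
  }
  if (file.exists(o("hot_gene_summary.tsv"))) {
    hs <- readr::read_tsv(o("hot_gene_summary.tsv"), progress = FALSE,
                          col_types = readr::cols())
    tot <- sum(hs$n_hot)
    lines <- c(lines, "## Exceptionally studied gene-years",
               if (tot == 0) "No significant hot gene-years: none detected." else
                 c(sprintf("Total hot gene-years: %d across %d years.", tot, nrow(hs)),
                   utils::capture.output(print(as.data.frame(
                     hs[hs$n_hot > 0, , drop = FALSE]), row.names = FALSE))),
               "")
  } else warning("hot-gene outputs missing")
  writeLines(lines, o("report.md"))
  invisible(lines)
}
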