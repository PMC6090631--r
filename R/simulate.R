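#' Parameters of the saturating publication-rate model
#'
#' The model predicts the expected number of publications on gene *i* in
#' year *t*+1 from the gene's cumulative publication count \eqn{P_{i,t}} and
#' the cross-gene mean cumulative count \eqn{P^*_t}:
#' \deqn{\Delta P_{i,t+1} = \frac{k_1 P^*_t + k_2 P_{i,t} + k_3}
#'       {1 + (P^*_t / P_S)^{\alpha}}.}
#' `k1` scales the field-wide (cohort) momentum, `k2` the gene's own
#' preferential-attachment momentum, and `k3` is the basal rate for a
#' never-studied gene; `P_S` and `alpha` set the scale and sharpness of the
#' saturation of overall publication rates. All five are shared across
#' genes. The defaults are the maximum-likelihood values estimated on the
#' human gene literature over 1950-2015, and define the simulator's
#' reference world.
#'
#' @param k1,k2,k3 non-negative rate parameters (publications/year units)
#' @param P_S positive saturation scale, in cumulative publications
#' @param alpha positive saturation exponent
#' @return named numeric vector of class `rate_params`
#' @export
rate_params <- function(k1 = 0.0214, k2 = 0.225, k3 = 0.00288,
                        P_S = 24.1, alpha = 1.67) {
  p <- c(k1 = k1, k2 = k2, k3 = k3, P_S = P_S, alpha = alpha)
  if (any(!is.finite(p)) || any(p[c("k1", "k2", "k3")] < 0) ||
      p["P_S"] <= 0 || p["alpha"] <= 0) {
    stop("rate parameters must be finite, k's >= 0, P_S > 0, alpha > 0")
  }
  structure(p, class = "rate_params")
}

#' Simulation configuration
#'
#' The stated world of the generator: per-gene annual counts are Poisson
#' with mean given by the saturating rate model evaluated self-consistently
#' on the realized counts, optionally scaled by a per-gene log-normal
#' heterogeneity multiplier. Defaults match the fitting scale used for
#' parameter-recovery checks: 5,000 genes over 1950-2015, the published
#' parameter values, no heterogeneity.
#'
#' @param n_genes number of genes (>= 1)
#' @param year_range integer length-2 `(start, end)`, start < end
#' @param params a [rate_params()] vector
#' @param heterogeneity_sd standard deviation (log scale) of the per-gene
#'   multiplier on the model mean; 0 = the pure shared-parameter model
#' @param seed integer RNG seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_genes = 5000L, year_range = c(1950L, 2015L),
                       params = rate_params(), heterogeneity_sd = 0,
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(year_range) == 2,
            year_range[1] < year_range[2], heterogeneity_sd >= 0)
  if (!inherits(params, "rate_params")) params <- do.call(rate_params, as.list(params))
  structure(list(n_genes = as.integer(n_genes),
                 year_range = as.integer(year_range),
                 params = params,
                 heterogeneity_sd = heterogeneity_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate per-gene publication histories
#'
#' Draws annual counts year by year: in year *t*+1 gene *i* receives
#' `Poisson(m_i * dP)` publications, where `dP` is the rate-model mean
#' evaluated at the realized cumulative counts and the realized cross-gene
#' mean, and `m_i` is the gene's heterogeneity multiplier (identically 1
#' when `heterogeneity_sd = 0`). Cumulative baselines start at zero: years
#' before the span are not simulated. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()]
#' @return a [pub_history()] with gene ids `1..n_genes`; the realized
#'   heterogeneity multipliers are attached as attribute `multipliers`.
#' @export
simulate_histories <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$params
  if (any(p <= 0)) stop("simulation requires strictly positive parameters")
  set.seed(cfg$seed)
  years <- seq.int(cfg$year_range[1], cfg$year_range[2])
  ng <- cfg$n_genes
  m <- if (cfg$heterogeneity_sd > 0) {
    stats::rlnorm(ng, meanlog = -cfg$heterogeneity_sd^2 / 2,
                  sdlog = cfg$heterogeneity_sd)
  } else {
    rep(1, ng)
  }
  X <- matrix(0L, nrow = ng, ncol = length(years),
              dimnames = list(seq_len(ng), years))
  cum <- numeric(ng)
  for (j in seq_along(years)) {
    ps <- mean(cum)
    lam <- m * (p["k1"] * ps + p["k2"] * cum + p["k3"]) /
      (1 + (ps / p["P_S"])^p["alpha"])
    x <- stats::rpois(ng, lam)
    X[, j] <- x
    cum <- cum + x
  }
  h <- pub_history(X, years, baseline = 0)
  attr(h, "multipliers") <- m
  h
}

#' A schedule of GWAS association shocks
#'
#' Each shock marks one gene's first GWAS association: in the association
#' year `t0` and the following `window - 1` years the gene receives extra
#' publications (an additive Poisson boost by default), and the shock
#' carries the association's p-value, odds ratio and trait class for the
#' catalog table.
#'
#' @param gene_id integer gene ids (must exist in the histories)
#' @param t0 integer association years
#' @param boost non-negative extra Poisson mean per window year
#' @param window window length in years, default 3
#' @param p_value association p-values; NA = draw at table-generation time
#' @param odds_ratio odds ratios; NA = draw at table-generation time
#' @param trait_class categorical trait label
#' @return tibble of shocks
#' @export
gwas_shocks <- function(gene_id, t0, boost, window = 3L,
                        p_value = NA_real_, odds_ratio = NA_real_,
                        trait_class = "complex_disease") {
  stopifnot(all(boost >= 0), all(window >= 1))
  tibble::tibble(gene_id = as.integer(gene_id), t0 = as.integer(t0),
                 boost = as.numeric(boost), window = as.integer(window),
                 p_value = p_value, odds_ratio = odds_ratio,
                 trait_class = trait_class)
}

#' Inject GWAS publication shocks into simulated histories
#'
#' For each shock, the gene's counts in years `t0 .. t0+window-1` are
#' incremented by independent Poisson(`boost`) draws (additive mode) or by
#' Poisson(`(boost - 1) * observed`) draws (multiplicative mode, where
#' `boost` acts as a rate multiplier on the realized counts). All other
#' gene-years are untouched.
#'
#' @param histories a [pub_history()]
#' @param shocks a [gwas_shocks()] tibble
#' @param seed RNG seed for the boost draws
#' @param mode `"additive"` (default) or `"multiplicative"`
#' @return the updated `pub_history`
#' @export
inject_gwas_shocks <- function(histories, shocks, seed = 1L,
                               mode = c("additive", "multiplicative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(histories, "pub_history"))
  missing <- setdiff(as.character(shocks$gene_id), rownames(histories$counts))
  if (length(missing)) {
    stop("shock gene(s) not in histories: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  if (any(shocks$t0 < histories$years[1] |
          shocks$t0 > histories$years[length(histories$years)])) {
    stop("shock year t0 outside the history span")
  }
  set.seed(seed)
  X <- histories$counts
  for (i in seq_len(nrow(shocks))) {
    g <- as.character(shocks$gene_id[i])
    yrs <- shocks$t0[i] + seq_len(shocks$window[i]) - 1L
    yrs <- yrs[yrs <= histories$years[length(histories$years)]]
    cols <- match(yrs, histories$years)
    if (mode == "additive") {
      extra <- stats::rpois(length(cols), shocks$boost[i])
    } else {
      extra <- stats::rpois(length(cols),
                            pmax(shocks$boost[i] - 1, 0) * X[g, cols])
    }
    X[g, cols] <- X[g, cols] + extra
  }
  out <- pub_history(X, histories$years, histories$baseline)
  attr(out, "multipliers") <- attr(histories, "multipliers")
  out
}

#' Generate a GWAS-catalog-dialect association table
#'
#' One catalog row per shock. Unless specified in the shock schedule,
#' `-log10(p)` is uniform on [5, 30] and odds ratios are log-normal
#' (meanlog 0.15, sdlog 0.2) with symmetric confidence intervals on the log
#' scale; a risk-allele frequency is always reported so the values are
#' recognized as odds ratios on re-ingestion. Dates fall at mid-year of
#' `t0` unless a `month` column is present in the shocks. Variant positions
#' are placed at the midpoint of the gene body given in `gene_info`.
#'
#' @param shocks a [gwas_shocks()] tibble
#' @param gene_info tibble `gene_id`, `chrom`, `start`, `end`
#' @param seed RNG seed
#' @param trait_uri_base URI prefix for trait ids
#' @return tibble in catalog dialect, ready for [write_fixture_bundle()]
#' @export
generate_association_table <- function(shocks, gene_info, seed = 1L,
                                       trait_uri_base = "http://www.ebi.ac.uk/efo/") {
  set.seed(seed)
  n <- nrow(shocks)
  cols <- c("SNPS", "CHR_ID", "CHR_POS", "MAPPED_GENE", "P-VALUE",
            "OR or BETA", "95% CI (TEXT)", "RISK ALLELE FREQUENCY", "DATE",
            "MAPPED_TRAIT_URI", "JOURNAL")
  if (n == 0L) {
    out <- tibble::as_tibble(stats::setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  gi <- gene_info[match(shocks$gene_id, gene_info$gene_id), , drop = FALSE]
  if (anyNA(gi$gene_id)) stop("shock gene(s) missing from gene_info")
  p <- ifelse(is.na(shocks$p_value), 10^-stats::runif(n, 5, 30), shocks$p_value)
  or <- ifelse(is.na(shocks$odds_ratio),
               stats::rlnorm(n, meanlog = 0.15, sdlog = 0.2), shocks$odds_ratio)
  half <- 0.07  # symmetric half-width of the CI on the log-OR scale
  ci <- sprintf("[%.2f-%.2f]", or * exp(-half), or * exp(half))
  month <- if ("month" %in% names(shocks)) shocks$month else rep(7L, n)
  date <- sprintf("%04d-%02d-01", shocks$t0, month)
  trait <- sprintf("EFO_%07d", 100 + as.integer(factor(shocks$trait_class)))
  tibble::tibble(
    "SNPS" = sprintf("rs%06d", seq_len(n)),
    "CHR_ID" = as.character(gi$chrom),
    "CHR_POS" = as.character((gi$start + gi$end) %/% 2L),
    "MAPPED_GENE" = as.character(shocks$gene_id),
    "P-VALUE" = format(p, digits = 3, scientific = TRUE, trim = TRUE),
    "OR or BETA" = sprintf("%.4f", or),
    "95% CI (TEXT)" = ci,
    "RISK ALLELE FREQUENCY" = sprintf("%.2f", stats::runif(n, 0.05, 0.95)),
    "DATE" = date,
    "MAPPED_TRAIT_URI" = paste0(trait_uri_base, trait),
    "JOURNAL" = "Synth J Genomics"
  )
}

#' Write a self-consistent synthetic input bundle
#'
#' Emits the full set of ingestion inputs for a simulated world:
#' `gene2pubmed.tsv` (one synthetic pmid per publication), `pubmed_years.tsv`,
#' `genemap2.tsv` (OMIM dialect, built from the class labels),
#' `gwas_catalog.tsv`, `efo_terms.txt` and `gene_info.tsv`. The bundle
#' round-trips: [ingest_bundle()] on the written files reproduces the
#' histories, class labels and association records exactly, and writing
#' twice from the same inputs is byte-identical.
#'
#' @param histories a [pub_history()]
#' @param omim tibble `gene_id`, `trait_kind` (may be empty) standing for
#'   the OMIM-derived labels
#' @param catalog catalog-dialect tibble from [generate_association_table()]
#' @param out_dir output directory (created if needed)
#' @param gene_info optional gene coordinate table; autogenerated
#'   deterministically (1 gene per 2 Mb along one synthetic chromosome)
#'   when NULL
#' @return invisible named vector of file paths
#' @export
write_fixture_bundle <- function(histories, omim, catalog, out_dir,
                                 gene_info = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory ", out_dir)
  }
  gids <- as.integer(rownames(histories$counts))
  if (is.null(gene_info)) gene_info <- synthetic_gene_info(gids)

  # one synthetic pmid per (gene, year, k) publication unit
  idx <- which(histories$counts > 0, arr.ind = TRUE)
  reps <- histories$counts[idx]
  gene <- rep(gids[idx[, 1]], reps)
  year <- rep(histories$years[idx[, 2]], reps)
  ord <- order(gene, year)
  gene <- gene[ord]; year <- year[ord]
  pmid <- seq_along(gene) + 10000000L
  g2p <- tibble::tibble(tax_id = 9606L, GeneID = gene, PubMed_ID = pmid)
  ytab <- tibble::tibble(PubMed_ID = pmid, year_reported = year, year_e = "")

  genemap <- tibble::tibble(
    "Entrez Gene ID" = omim$gene_id,
    "Phenotype" = ifelse(omim$trait_kind == "complex_multifactorial",
                         "{Synthetic complex trait}", "Synthetic mendelian trait"),
    "Confidence" = "confirmed"
  )
  efo <- sort(unique(sub("^.*/", "", catalog$MAPPED_TRAIT_URI)))

  paths <- c(
    gene2pubmed = file.path(out_dir, "gene2pubmed.tsv"),
    years = file.path(out_dir, "pubmed_years.tsv"),
    omim = file.path(out_dir, "genemap2.tsv"),
    gwas = file.path(out_dir, "gwas_catalog.tsv"),
    efo_terms = file.path(out_dir, "efo_terms.txt"),
    genes = file.path(out_dir, "gene_info.tsv")
  )
  # NCBI-style '#' header line
  con <- file(paths["gene2pubmed"], "w")
  writeLines("#tax_id\tGeneID\tPubMed_ID", con)
  utils::write.table(g2p, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)
  readr::write_tsv(ytab, paths["years"], progress = FALSE)
  readr::write_tsv(genemap, paths["omim"], progress = FALSE)
  readr::write_tsv(catalog, paths["gwas"], progress = FALSE)
  writeLines(efo, paths["efo_terms"])
  gi_out <- tibble::tibble(GeneID = gene_info$gene_id, chrom = gene_info$chrom,
                           start = gene_info$start, end = gene_info$end)
  readr::write_tsv(gi_out, paths["genes"], progress = FALSE)
  invisible(paths)
}

#' Deterministic synthetic gene coordinates
#'
#' Non-overlapping 100-kb gene bodies spaced 2 Mb apart, tiled 500 genes
#' per synthetic chromosome, so every midpoint variant maps unambiguously
#' back to its gene and positions stay within integer range.
#'
#' @param gene_ids integer vector
#' @return tibble `gene_id`, `chrom`, `start`, `end` (1-based inclusive)
#' @export
synthetic_gene_info <- function(gene_ids) {
  gene_ids <- sort(unique(as.integer(gene_ids)))
  i <- seq_along(gene_ids) - 1L
  start <- 1L + (i %% 500L) * 2000000L
  tibble::tibble(gene_id = gene_ids, chrom = as.character(1L + i %/% 500L),
                 start = start, end = start + 99999L)
}
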