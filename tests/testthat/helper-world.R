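# Shared fixture builders. Everything is generated in code; no data files.

# a small handcrafted history set: 4 genes, 6 years
tiny_history <- function() {
  counts <- rbind(
    `1` = c(0, 1, 0, 2, 1, 0),
    `2` = c(1, 1, 1, 1, 1, 1),
    `3` = c(0, 0, 0, 0, 0, 0),
    `4` = c(5, 0, 0, 0, 0, 3)
  )
  colnames(counts) <- 2000:2005
  pub_history(counts, 2000:2005, baseline = c(0, 2, 0, 0))
}

# simulated null world plus a random never-boosted "GWAS" designation;
# returns the pieces needed for excess-statistic checks
null_excess_world <- function(n_genes = 1500, years = c(1950L, 2015L),
                              n_gwas = 400, t0_range = c(2003L, 2012L),
                              seed = 1) {
  h <- simulate_histories(sim_config(n_genes = n_genes, year_range = years,
                                     seed = seed))
  set.seed(seed + 1000L)
  gwas_ids <- sample.int(n_genes, n_gwas)
  t0 <- sample(seq.int(t0_range[1], t0_range[2]), n_gwas, replace = TRUE)
  classes <- tibble::tibble(
    gene_id = seq_len(n_genes),
    label = ifelse(seq_len(n_genes) %in% gwas_ids, "complex", "none"),
    first_gwas_year = NA_integer_,
    first_assoc_p = NA_real_,
    first_assoc_or = NA_real_
  )
  classes$first_gwas_year[gwas_ids] <- t0
  classes$first_assoc_p[gwas_ids] <- 10^-runif(n_gwas, 5, 30)
  classes$first_assoc_or[gwas_ids] <- rlnorm(n_gwas, 0.15, 0.2)
  assoc <- tibble::tibble(
    gene_id = gwas_ids, year = t0,
    p_value = classes$first_assoc_p[gwas_ids],
    odds_ratio = classes$first_assoc_or[gwas_ids],
    or_ci_lower = classes$first_assoc_or[gwas_ids] * exp(-0.07),
    pub_date = as.Date(sprintf("%d-%02d-01", t0,
                               sample(1:12, n_gwas, replace = TRUE))),
    trait_id = "EFO_0000101"
  )
  list(histories = h, classes = classes, associations = assoc,
       gwas_ids = gwas_ids, t0 = t0)
}

# world in which the GWAS publication boost declines linearly with the
# association year: the generator's analogue of a waning GWAS effect
declining_boost_world <- function(seed, n_genes = 400,
                                  years = c(1950L, 2014L),
                                  n_gwas = 80, t0_range = c(1996L, 2012L),
                                  boost0 = 12, slope = 0.7) {
  w <- null_excess_world(n_genes = n_genes, years = years, n_gwas = n_gwas,
                         t0_range = t0_range, seed = seed)
  boost <- pmax(boost0 - slope * (w$t0 - t0_range[1]), 0)
  shocks <- gwas_shocks(w$gwas_ids, w$t0, boost)
  w$histories <- inject_gwas_shocks(w$histories, shocks, seed = seed + 2000L)
  w$shocks <- shocks
  w
}

# brute-force Gini: mean absolute pairwise difference over 2 n^2 xbar
gini_bruteforce <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# exhaustive control match: lexicographic minimum of the |cum difference|
# sequence over descending comparison years (full-depth matrix ordering)
match_control_bruteforce <- function(gwas_gene, candidates, histories, t0) {
  years <- histories$years
  cmp_years <- seq.int(t0 - 1L, years[1])
  if (t0 - 1L < years[1]) cmp_years <- years[1] - 1L
  seq_for <- function(g) {
    vapply(cmp_years, function(y) {
      if (y < years[1]) histories$baseline[as.character(g)]
      else cum_at(histories, y)[as.character(g)]
    }, numeric(1))
  }
  target <- seq_for(gwas_gene)
  D <- vapply(candidates, function(g) abs(seq_for(g) - target),
              numeric(length(cmp_years)))
  D <- matrix(D, nrow = length(cmp_years))
  ord <- do.call(order, c(split(D, row(D)), list(candidates)))
  best <- ord[1]
  # all candidates whose full column equals the best column are tied
  tied <- which(colSums(abs(D - D[, best])) == 0)
  sort(candidates[tied])
}
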