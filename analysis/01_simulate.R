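#!/usr/bin/env Rscript
# Stage 1: build the reference synthetic world.
#
# 2,000 genes over 1950-2015, annual counts Poisson with the saturating
# rate-model mean at the published parameter values; 150 genes receive a
# first GWAS association between 1996 and 2012 whose publication boost
# declines linearly with the association year (the waning-GWAS-effect
# world). The full input bundle (gene2pubmed/year-table/genemap/catalog
# dialects) is written so stage 2 exercises the real parsers.

suppressMessages(library(pubpulse))

out <- "results/world"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

set.seed(seed)
h <- simulate_histories(sim_config(n_genes = 2000L, year_range = c(1950L, 2015L),
                                   seed = seed))
gwas_ids <- sample.int(2000L, 150L)
t0 <- sample(1996:2012, 150L, replace = TRUE)
boost <- pmax(12 - 0.7 * (t0 - 1996L), 0)
shocks <- gwas_shocks(gwas_ids, t0, boost)
shocks$month <- sample(1:12, 150L, replace = TRUE)
h <- inject_gwas_shocks(h, shocks, seed = seed + 1L)

# a Mendelian-only stratum among the never-GWAS genes, for the rank analysis
mend <- sample(setdiff(1:2000, gwas_ids), 120L)
omim <- tibble::tibble(gene_id = sort(mend), trait_kind = "mendelian")

gi <- synthetic_gene_info(1:2000)
catalog <- generate_association_table(shocks, gi, seed = seed + 2L)
paths <- write_fixture_bundle(h, omim, catalog, out, gene_info = gi)

cat("World written to", out, "\n")
cat(sprintf("  %d genes, %s publications, %d GWAS shocks (boost %.0f down to %.0f/yr)\n",
            nrow(h$counts), format(sum(h$counts), big.mark = ","),
            nrow(shocks), max(boost), min(boost)))
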