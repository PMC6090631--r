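#!/usr/bin/env Rscript
# Stage 2: ingest the input bundle through the catalog/genemap/gene2pubmed
# parsers, with filter accounting. Saves the reconstructed objects for the
# downstream stages.

suppressMessages(library(pubpulse))

paths <- list(gene2pubmed = "results/world/gene2pubmed.tsv",
              years = "results/world/pubmed_years.tsv",
              omim = "results/world/genemap2.tsv",
              gwas = "results/world/gwas_catalog.tsv",
              efo_terms = "results/world/efo_terms.txt",
              genes = "results/world/gene_info.tsv")
stopifnot(all(file.exists(unlist(paths))))

ing <- do.call(ingest_bundle, c(paths, list(year_range = c(1950L, 2015L))))

dir.create("results/ingest", showWarnings = FALSE)
readr::write_tsv(ing$classes, "results/ingest/classes.tsv")
readr::write_tsv(ing$associations, "results/ingest/associations.tsv")
readr::write_tsv(tibble::as_tibble(ing$histories$counts, rownames = "gene_id"),
                 "results/ingest/annual_counts.tsv")

cat("Filter accounting:\n")
print(ing$accounting)
cat(sprintf("Classes: %s\n",
            paste(names(table(ing$classes$label)), table(ing$classes$label),
                  sep = "=", collapse = ", ")))
cat(sprintf("%d disease associations over %d genes\n",
            nrow(ing$associations), length(unique(ing$associations$gene_id))))
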