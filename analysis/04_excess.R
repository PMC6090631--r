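#!/usr/bin/env Rscript
# Stage 4: the matched-control publication excess. Each newly associated
# gene is matched to the never-GWAS gene with the closest prior publication
# history; the excess over the 3-year follow-up window is normalized by
# sqrt(recent publications) and modelled on its predictors.

suppressMessages(library(pubpulse))

counts <- as.matrix(readr::read_tsv("results/ingest/annual_counts.tsv",
                                    show_col_types = FALSE))
rownames(counts) <- counts[, "gene_id"]
h <- pub_history(counts[, -1], 1950:2015)
classes <- readr::read_tsv("results/ingest/classes.tsv", show_col_types = FALSE)
assoc <- readr::read_tsv("results/ingest/associations.tsv", show_col_types = FALSE)

rec <- build_excess_records(h, classes, assoc, window = 3L)
loc <- excess_location_test(rec$norm_excess)
cors <- predictor_correlations(rec)
reg <- fit_excess_regression(rec)
ts <- total_excess_timeseries(rec, bin_months = 6L)
rec_hc <- apply_robustness_filters(rec, p_max = 1e-8)

dir.create("results/excess", showWarnings = FALSE)
out_rec <- rec
out_rec$control_ids <- vapply(out_rec$control_ids, paste, character(1), collapse = ",")
readr::write_tsv(out_rec, "results/excess/records.tsv")
readr::write_tsv(reg$coefficients, "results/excess/regression.tsv")
readr::write_tsv(cors, "results/excess/correlations.tsv")
readr::write_tsv(ts, "results/excess/timeseries.tsv")
jsonlite::write_json(list(location = loc, n_high_confidence = nrow(rec_hc)),
                     "results/excess/location.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("N = %d newly associated genes (%d ambiguous matches averaged)\n",
            nrow(rec), sum(rec$n_controls > 1)))
cat(sprintf("Mean normalized excess %.2f (one-sample t = %.1f, p = %.2g)\n",
            loc$mean, loc$t, loc$p))
cat(sprintf("Mean raw excess %.2f publications over the 3-year window\n",
            mean(rec$raw_excess)))
cat("Spearman correlations with the normalized excess:\n")
print(as.data.frame(cors), digits = 3)
cat("Regression (Table-1 shape):\n")
print(as.data.frame(reg$coefficients), digits = 3)
cat(sprintf("Date coefficient %.3f: the per-gene GWAS effect declines with time.\n",
            reg$coefficients$estimate[reg$coefficients$term == "assoc_date"]))
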