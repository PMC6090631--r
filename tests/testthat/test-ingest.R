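test_that("gene2pubmed parsing filters by taxon, dedupes and accounts for rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#tax_id\tGeneID\tPubMed_ID",
               "9606\t10\t100",
               "9606\t11\t101",
               "4932\t99\t102",
               "9606\t10\t100",     # duplicate
               "9606\tbad\t103"),   # malformed
             f)
  expect_warning(links <- parse_gene2pubmed(f, taxon = 9606L), "malformed")
  expect_equal(nrow(links), 2L)
  expect_setequal(links$gene_id, c(10L, 11L))
  acc <- attr(links, "accounting")
  # accounting identity: rows = links + taxon-filtered + duplicates + malformed
  expect_equal(unname(acc["rows"]),
               unname(acc["links"] + acc["taxon_dropped"] +
                        acc["duplicates"] + acc["malformed"]))
  expect_error(suppressWarnings(parse_gene2pubmed(f, taxon = 1234L)), "no links")
})

test_that("publication year is the earliest of reported and electronic year", {
  links <- tibble::tibble(gene_id = c(1L, 1L, 2L), pmid = c(7L, 8L, 9L))
  ytab <- tibble::tibble(pmid = c("7", "8", "9"),
                         year_reported = c("2007", "2007", ""),
                         year_e = c("2006", "", ""))
  expect_warning(out <- assign_pub_years(links, ytab), "no publication year")
  expect_equal(out$year[out$pmid == 7], 2006L)  # min of the two fields
  expect_equal(out$year[out$pmid == 8], 2007L)  # only reported present
  expect_false(9L %in% out$pmid)                # no year at all -> dropped
  expect_equal(unname(attr(out, "accounting")["missing_year"]), 1)
})

test_that("OMIM genemap parsing applies confidence and phenotype-flag filters", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    "Entrez Gene ID" = c("1", "2", "3", "4", "5", ""),
    "Phenotype" = c("Mendelian thing", "{Complex thing}", "?Dubious thing",
                    "[Not a disease]", "Provisional thing", "Orphan"),
    "Confidence" = c("confirmed", "confirmed", "confirmed", "confirmed",
                     "provisional", "confirmed")
  ), f)
  om <- parse_omim_genemap(f)
  expect_equal(om$gene_id, c(1L, 2L))
  expect_equal(om$trait_kind, c("mendelian", "complex_multifactorial"))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(x = 1), f2)
  expect_error(parse_omim_genemap(f2), "lacks column")
})

test_that("variant-gene mapping follows the 500 kb closest-gene rule", {
  genes <- tibble::tibble(gene_id = c(10L, 20L, 30L),
                          chrom = c("1", "1", "1"),
                          start = c(1000L, 5000L, 2000000L),
                          end = c(2000L, 6000L, 2100000L))
  v <- function(pos, chrom = "1") tibble::tibble(variant_id = "v", chrom = chrom, pos = pos)
  # inside exactly one gene, another 3 kb away -> the containing gene only
  hit <- map_variant_to_genes(v(1500L), genes)
  expect_equal(hit$gene_id, 10L)
  expect_equal(hit$distance, 0L)
  # between genes: nearest wins
  expect_equal(map_variant_to_genes(v(4500L), genes)$gene_id, 20L)
  # beyond 500 kb of everything -> no gene
  expect_equal(nrow(map_variant_to_genes(v(700000L), genes)), 0L)
  # exactly at the 500 kb boundary is kept, 1 bp beyond is not
  expect_equal(map_variant_to_genes(v(2100000L + 500000L), genes)$gene_id, 30L)
  expect_equal(nrow(map_variant_to_genes(v(2100000L + 500001L), genes)), 0L)
  # equidistant tie -> smaller gene_id
  expect_equal(map_variant_to_genes(v(3500L), genes)$gene_id, 10L)
  # unknown chromosome -> empty with warning
  expect_warning(none <- map_variant_to_genes(v(1500L, chrom = "7"), genes),
                 "without genes")
  expect_equal(nrow(none), 0L)
})

test_that("variant inside two overlapping gene bodies maps to both", {
  genes <- tibble::tibble(gene_id = c(1L, 2L), chrom = "1",
                          start = c(100L, 500L), end = c(1000L, 1500L))
  hit <- map_variant_to_genes(tibble::tibble(variant_id = "v", chrom = "1",
                                             pos = 700L), genes)
  expect_setequal(hit$gene_id, c(1L, 2L))
  expect_true(all(hit$distance == 0L))
})

test_that("nearest-gene mapping agrees with an exhaustive interval scan", {
  set.seed(11)
  for (rep in 1:20) {
    ngene <- 30
    start <- sort(sample.int(3e6, ngene))
    genes <- tibble::tibble(gene_id = sample.int(1000, ngene),
                            chrom = "1", start = start,
                            end = start + sample.int(5e4, ngene))
    pos <- sample.int(3.2e6, 40)
    vars <- tibble::tibble(variant_id = paste0("v", seq_along(pos)),
                           chrom = "1", pos = pos)
    got <- map_variant_to_genes(vars, genes, max_distance = 5e5)
    # oracle: per-variant loop over every gene interval
    for (i in seq_along(pos)) {
      d <- ifelse(pos[i] >= genes$start & pos[i] <= genes$end, 0L,
                  pmin(abs(pos[i] - genes$start), abs(pos[i] - genes$end)))
      inside <- which(d == 0L)
      expected <- if (length(inside) > 0) {
        sort(genes$gene_id[inside])
      } else if (min(d) <= 5e5) {
        cand <- genes$gene_id[d == min(d)]
        min(cand)
      } else {
        integer(0)
      }
      expect_equal(sort(got$gene_id[got$variant_id == paste0("v", i)]),
                   expected)
    }
  }
})

test_that("disease-trait filtering keeps only terms in the disease set", {
  assoc <- tibble::tibble(gene_id = 1:3,
                          trait_id = c("EFO_0000270", "EFO_0004339", "EFO_9999999"))
  expect_warning(out <- filter_disease_traits(assoc, "EFO_0000270"), "removed")
  expect_equal(out$gene_id, 1L)
  expect_error(filter_disease_traits(assoc, character(0)), "empty")
})

test_that("gene classification partitions the universe by the stated rules", {
  omim <- tibble::tibble(
    gene_id = c(1L, 2L, 3L, 3L, 5L),
    trait_kind = c("mendelian", "complex_multifactorial", "mendelian",
                   "complex_multifactorial", "mendelian")
  )
  assoc <- tibble::tibble(gene_id = c(4L, 5L, 4L), year = c(2008L, 2010L, 2006L),
                          p_value = c(1e-9, 1e-12, 1e-7),
                          odds_ratio = c(1.2, NA, 1.4))
  cls <- classify_genes(omim, assoc, gene_universe = 1:6)
  expect_equal(cls$label, c("mendelian", "complex", "both", "complex", "both", "none"))
  # partition: labels cover the whole universe, counts sum to its size
  expect_equal(sum(table(cls$label)), 6L)
  # earliest surviving association sets the first-GWAS year
  expect_equal(cls$first_gwas_year[cls$gene_id == 4L], 2006L)
  # strongest (smallest-p) first-year association supplies p and OR
  expect_equal(cls$first_assoc_p[cls$gene_id == 4L], 1e-7)
  expect_equal(cls$first_assoc_or[cls$gene_id == 4L], 1.4)
  expect_true(is.na(cls$first_gwas_year[cls$gene_id == 1L]))
})

test_that("history building conserves links, zero-fills and folds pre-span years", {
  links <- tibble::tibble(
    gene_id = c(1L, 1L, 1L, 2L, 2L, 3L),
    pmid = 1:6,
    year = c(2001L, 2001L, 2003L, 1948L, 2002L, 2010L)
  )
  h <- build_histories(links, gene_universe = 1:4, year_range = c(2000L, 2005L))
  expect_equal(unname(cum_at(h, 2003L)["1"]), 3)          # {2001:2, 2003:1}
  expect_equal(unname(h$baseline["2"]), 1)                # pre-span fold-in
  expect_equal(unname(cum_at(h, 2005L)["2"]), 2)
  expect_equal(sum(h$counts["4", ]), 0)                   # zero-publication gene
  # conservation: in-span counts + baselines = links kept (gene 3 is post-span)
  expect_equal(sum(h$counts) + sum(h$baseline), 5)
  cm <- cum_matrix(h)
  expect_true(all(apply(cm, 1, function(r) all(diff(r) >= 0))))
})

test_that("catalog parsing extracts odds ratios only under the recognition rule", {
  genes <- synthetic_gene_info(c(10L, 20L))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    "SNPS" = c("rs1", "rs2", "rs3", "rs4"),
    "CHR_ID" = "1",
    "CHR_POS" = as.character(genes$start[c(1, 1, 2, 2)] + 10L),
    "MAPPED_GENE" = c("10", "10", "20", "20"),
    "P-VALUE" = c("1e-12", "1e-8", "2e-6", "1e-3"),
    "OR or BETA" = c("1.25", "0.15", "1.10", "1.5"),
    "95% CI (TEXT)" = c("[1.10-1.40]", "[0.10-0.20] unit increase",
                        "[1.02-1.19]", "[1.2-1.8]"),
    "RISK ALLELE FREQUENCY" = c("0.30", "0.25", "NR", "0.5"),
    "DATE" = c("2009-03-01", "2010-06-01", "2011-01-01", "2012-01-01"),
    "MAPPED_TRAIT_URI" = "http://www.ebi.ac.uk/efo/EFO_0000270",
    "JOURNAL" = "J"
  ), f)
  expect_warning(out <- parse_gwas_catalog(f, genes), "inclusion rule")
  expect_equal(nrow(out), 3L)  # rs4 fails the 1e-5 inclusion threshold
  # rs1: RAF present, unitless CI -> odds ratio with its CI lower bound
  expect_equal(out$odds_ratio[out$variant_id == "rs1"], 1.25)
  expect_equal(out$or_ci_lower[out$variant_id == "rs1"], 1.10)
  # rs2: CI annotated with units -> beta, not an odds ratio
  expect_true(is.na(out$odds_ratio[out$variant_id == "rs2"]))
  # rs3: no risk-allele frequency -> not recognized as an odds ratio
  expect_true(is.na(out$odds_ratio[out$variant_id == "rs3"]))
  expect_equal(out$gene_id, c(10L, 10L, 20L))
  expect_equal(out$year, c(2009L, 2010L, 2011L))
})
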