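#' Read a gene2pubmed-dialect link table
#'
#' Parses the NCBI-style tab-separated table of (tax_id, GeneID, PubMed_ID)
#' rows, keeps the requested taxon, and collapses duplicate (gene, pmid)
#' pairs. Lines starting with `#` are treated as headers. Malformed rows
#' (non-numeric fields, wrong arity) are skipped with a warning and counted
#' in the accounting attribute.
#'
#' @param path path to the TSV file
#' @param taxon integer NCBI taxon id to retain (9606 = human)
#' @return tibble with columns `gene_id`, `pmid` (both integer), one row per
#'   unique link; attribute `accounting` records rows read, taxon-filtered,
#'   duplicated and malformed.
#' @export
parse_gene2pubmed <- function(path, taxon = 9606L) {
  raw <- readr::read_tsv(path, comment = "#",
                         col_names = c("tax_id", "gene_id", "pmid"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  n_rows <- nrow(raw)
  suppressWarnings({
    tax <- as.integer(raw$tax_id)
    gid <- as.integer(raw$gene_id)
    pm <- as.integer(raw$pmid)
  })
  bad <- is.na(tax) | is.na(gid) | is.na(pm)
  if (any(bad)) {
    warning(sum(bad), " malformed gene2pubmed row(s) skipped")
  }
  keep <- !bad & tax == taxon
  links <- tibble::tibble(gene_id = gid[keep], pmid = pm[keep])
  n_taxon_dropped <- sum(!bad) - nrow(links)
  n_before_dedupe <- nrow(links)
  links <- dplyr::distinct(links)
  if (nrow(links) == 0L) {
    stop("no links for taxon ", taxon, " in ", path)
  }
  attr(links, "accounting") <- c(rows = n_rows, malformed = sum(bad),
                                 taxon_dropped = n_taxon_dropped,
                                 duplicates = n_before_dedupe - nrow(links),
                                 links = nrow(links))
  links
}

#' Attach publication years to gene-publication links
#'
#' Each publication's year is the earliest of its reported publication year
#' and its electronic publication year (EYear); when only one is available
#' that one is used, and links whose publication has no usable year are
#' dropped with a warning. Non-numeric year fields are treated as absent.
#'
#' @param links tibble with `gene_id`, `pmid` (from [parse_gene2pubmed()])
#' @param year_table tibble with columns `pmid`, `year_reported`, `year_e`
#'   (empty string or NA for missing)
#' @return tibble `gene_id`, `pmid`, `year`; attribute `accounting` counts
#'   links dropped for missing years.
#' @export
assign_pub_years <- function(links, year_table) {
  suppressWarnings({
    yr <- as.integer(year_table$year_reported)
    ye <- as.integer(year_table$year_e)
  })
  year <- pmin(yr, ye, na.rm = TRUE)
  ytab <- tibble::tibble(pmid = as.integer(year_table$pmid), year = year)
  ytab <- ytab[!is.na(ytab$year), , drop = FALSE]
  out <- dplyr::inner_join(links, ytab, by = "pmid")
  n_dropped <- nrow(links) - nrow(out)
  if (n_dropped > 0L) {
    warning(n_dropped, " link(s) dropped: no publication year available")
  }
  acc <- attr(links, "accounting")
  attr(out, "accounting") <- c(acc, missing_year = n_dropped)
  out
}

#' Read a year table (pmid, reported year, electronic year)
#' @param path TSV with columns `PubMed_ID`, `year_reported`, `year_e`
#' @return tibble with `pmid`, `year_reported`, `year_e` as character
#' @export
read_year_table <- function(path) {
  yt <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  names(yt) <- c("pmid", "year_reported", "year_e")[seq_len(ncol(yt))]
  yt
}

#' Read a gene universe table with genomic intervals
#'
#' The gene universe is fixed by this table, not inferred from the link
#' table, so zero-publication genes exist and rank analyses cover all genes.
#' Coordinates in the file are 1-based inclusive.
#'
#' @param path TSV with columns `GeneID`, `chrom`, `start`, `end`
#' @return tibble `gene_id`, `chrom`, `start`, `end`
#' @export
read_gene_info <- function(path) {
  gi <- readr::read_tsv(path, col_types = "icii", progress = FALSE)
  names(gi) <- c("gene_id", "chrom", "start", "end")
  if (any(gi$end < gi$start)) stop("gene interval with end < start in ", path)
  gi
}

#' Parse an OMIM genemap-dialect gene-trait table
#'
#' Keeps only entries with a confidence code of "confirmed", an Entrez gene
#' id, and a disease phenotype. Following OMIM phenotype-string conventions,
#' a leading `?` marks a potentially spurious mapping (excluded), square
#' brackets `[...]` mark a non-disease trait (excluded), and curly braces
#' `{...}` mark susceptibility to complex multifactorial disease, which sets
#' the trait kind.
#'
#' @param path TSV file
#' @param columns named list mapping the roles `gene_id`, `phenotype`,
#'   `confidence` to column names in the file.
#' @return tibble `gene_id`, `trait_kind` (one of `"mendelian"`,
#'   `"complex_multifactorial"`), unique rows.
#' @export
parse_omim_genemap <- function(path,
                               columns = list(gene_id = "Entrez Gene ID",
                                              phenotype = "Phenotype",
                                              confidence = "Confidence")) {
  om <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- unlist(columns)
  miss <- setdiff(need, names(om))
  if (length(miss)) {
    stop("genemap file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  }
  gid <- suppressWarnings(as.integer(om[[columns$gene_id]]))
  phen <- trimws(om[[columns$phenotype]])
  conf <- tolower(trimws(om[[columns$confidence]]))
  keep <- !is.na(gid) & conf == "confirmed" & nzchar(phen)
  spurious <- startsWith(phen, "?")
  nondisease <- startsWith(phen, "[")
  complex_flag <- startsWith(phen, "{")
  keep <- keep & !spurious & !nondisease
  out <- tibble::tibble(
    gene_id = gid[keep],
    trait_kind = ifelse(complex_flag[keep], "complex_multifactorial", "mendelian")
  )
  dplyr::distinct(out)
}

#' Map variants to genes by genomic proximity
#'
#' Connects each variant to its closest gene when that gene lies within
#' `max_distance` base pairs (default 500 kb), and to both genes when the
#' variant falls inside two (or more) overlapping gene bodies. Distance is 0
#' inside a gene body and otherwise the number of base pairs to the nearer
#' interval end; ties between equidistant genes are broken toward the
#' smaller gene id so results are deterministic. Variants on chromosomes
#' absent from the gene table map to no gene, with a warning.
#'
#' @param variants tibble with `variant_id`, `chrom`, `pos` (1-based)
#' @param gene_intervals tibble `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [read_gene_info()]
#' @param max_distance maximum bp distance, default 5e5
#' @return tibble `variant_id`, `gene_id`, `distance`; zero, one or several
#'   rows per variant (several only for overlapping containing genes).
#' @export
map_variant_to_genes <- function(variants, gene_intervals, max_distance = 5e5) {
  gr_genes <- GenomicRanges::GRanges(
    seqnames = gene_intervals$chrom,
    ranges = IRanges::IRanges(start = gene_intervals$start, end = gene_intervals$end)
  )
  unknown <- !(variants$chrom %in% as.character(unique(gene_intervals$chrom)))
  if (any(unknown)) {
    warning(sum(unknown), " variant(s) on chromosomes without genes; unmapped")
  }
  vkeep <- variants[!unknown, , drop = FALSE]
  if (nrow(vkeep) == 0L) {
    return(tibble::tibble(variant_id = character(), gene_id = integer(),
                          distance = integer()))
  }
  gr_var <- GenomicRanges::GRanges(
    seqnames = vkeep$chrom,
    ranges = IRanges::IRanges(start = vkeep$pos, width = 1L)
  )
  # containment: variants inside gene bodies
  ov <- GenomicRanges::findOverlaps(gr_var, gr_genes)
  inside <- tibble::tibble(
    v = S4Vectors::queryHits(ov),
    gene_id = gene_intervals$gene_id[S4Vectors::subjectHits(ov)],
    distance = 0L
  )
  rows <- list()
  inside_v <- unique(inside$v)
  if (length(inside_v)) {
    # inside one gene -> that gene; inside several overlapping bodies -> all
    rows[[1]] <- inside
  }
  out_v <- setdiff(seq_along(gr_var), inside_v)
  if (length(out_v)) {
    # all genes within range of each outside variant; GRanges gap distance
    # is bp-between-ends minus one for a point query, so +1 = bp to the end
    near <- GenomicRanges::findOverlaps(gr_var[out_v], gr_genes,
                                        maxgap = max_distance)
    if (length(near)) {
      qh <- S4Vectors::queryHits(near)
      sh <- S4Vectors::subjectHits(near)
      gap <- GenomicRanges::distance(gr_var[out_v][qh], gr_genes[sh])
      cand <- tibble::tibble(
        v = out_v[qh],
        gene_id = gene_intervals$gene_id[sh],
        distance = gap + 1L
      )
      cand <- cand[cand$distance <= max_distance, , drop = FALSE]
      # nearest wins; equidistant ties go to the smaller gene id
      cand <- dplyr::slice_min(dplyr::group_by(cand, .data$v),
                               order_by = .data$distance, n = 1L)
      cand <- dplyr::slice_min(cand, order_by = .data$gene_id, n = 1L)
      rows[[2]] <- dplyr::ungroup(cand)
    }
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(variant_id = character(), gene_id = integer(),
                          distance = integer()))
  }
  res <- tibble::tibble(variant_id = vkeep$variant_id[hits$v],
                        gene_id = hits$gene_id,
                        distance = as.integer(hits$distance))
  dplyr::arrange(res, match(.data$variant_id, vkeep$variant_id), .data$gene_id)
}

#' Read an EFO disease-term list
#'
#' One term id per line (e.g. `EFO_0000270`); the set of descendants of the
#' ontology's "disease" term, precomputed outside the package.
#'
#' @param path text file of term ids
#' @return character vector of term ids
#' @export
read_efo_terms <- function(path) {
  terms <- readLines(path)
  terms <- trimws(terms)
  terms[nzchar(terms)]
}

#' Restrict associations to disease traits
#'
#' @param associations tibble with a `trait_id` column
#' @param efo_disease_terms character vector of disease term ids
#' @return the subset of `associations` whose trait is in the disease set;
#'   unknown traits are dropped with a warning.
#' @export
filter_disease_traits <- function(associations, efo_disease_terms) {
  if (length(efo_disease_terms) == 0L) {
    stop("empty EFO disease-term set")
  }
  keep <- associations$trait_id %in% efo_disease_terms
  if (any(!keep)) {
    warning(sum(!keep), " association(s) removed: trait not in disease set")
  }
  associations[keep, , drop = FALSE]
}

#' Parse a GWAS-catalog-dialect association table
#'
#' Reads the catalog TSV, maps each variant to gene(s) by coordinates
#' (falling back to the `MAPPED_GENE` column when coordinates are missing or
#' unmappable), and extracts p-values, odds ratios and publication dates.
#' Following the convention that the catalog's effect-size column holds
#' either an odds ratio or a beta, the value is taken as an odds ratio only
#' when a risk-allele frequency was reported and the confidence-interval
#' text carries no unit annotation.
#'
#' @param path catalog TSV with columns SNPS, CHR_ID, CHR_POS, MAPPED_GENE,
#'   P-VALUE, OR or BETA, 95% CI (TEXT), RISK ALLELE FREQUENCY, DATE,
#'   MAPPED_TRAIT_URI, JOURNAL
#' @param gene_intervals gene universe with coordinates, for variant mapping
#' @param p_max catalog inclusion threshold on the association p-value
#'   (default 1e-5); rows above it are dropped.
#' @return tibble of association records: `variant_id`, `gene_id`,
#'   `trait_id`, `p_value`, `odds_ratio`, `or_ci_lower`, `pub_date` (Date),
#'   `year`, `journal`; one row per (variant, gene) connection.
#' @export
parse_gwas_catalog <- function(path, gene_intervals, p_max = 1e-5) {
  cat_raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  need <- c("SNPS", "CHR_ID", "CHR_POS", "MAPPED_GENE", "P-VALUE",
            "OR or BETA", "95% CI (TEXT)", "DATE", "MAPPED_TRAIT_URI")
  miss <- setdiff(need, names(cat_raw))
  if (length(miss)) {
    stop("catalog file lacks column(s): ", paste(miss, collapse = ", "))
  }
  p <- suppressWarnings(as.numeric(cat_raw[["P-VALUE"]]))
  keep <- !is.na(p) & p > 0 & p <= p_max
  if (any(!keep)) {
    warning(sum(!keep), " catalog row(s) dropped by the p <= ", p_max, " inclusion rule")
  }
  cat_raw <- cat_raw[keep, , drop = FALSE]
  p <- p[keep]

  effect <- suppressWarnings(as.numeric(cat_raw[["OR or BETA"]]))
  ci_text <- cat_raw[["95% CI (TEXT)"]]
  raf <- if ("RISK ALLELE FREQUENCY" %in% names(cat_raw)) {
    suppressWarnings(as.numeric(cat_raw[["RISK ALLELE FREQUENCY"]]))
  } else {
    rep(NA_real_, nrow(cat_raw))
  }
  ci <- parse_ci_text(ci_text)
  # odds ratio only when risk-allele frequency reported and CI is unitless
  is_or <- !is.na(effect) & !is.na(raf) & !ci$has_unit
  odds_ratio <- ifelse(is_or, effect, NA_real_)
  or_ci_lower <- ifelse(is_or, ci$lower, NA_real_)

  pub_date <- as.Date(cat_raw$DATE)
  trait_id <- vapply(strsplit(cat_raw$MAPPED_TRAIT_URI, "/", fixed = TRUE),
                     function(x) x[length(x)], character(1))

  pos <- suppressWarnings(as.integer(cat_raw$CHR_POS))
  has_coord <- !is.na(pos) & !is.na(cat_raw$CHR_ID) & nzchar(cat_raw$CHR_ID)
  variants <- tibble::tibble(variant_id = paste0("row", seq_len(nrow(cat_raw))),
                             chrom = cat_raw$CHR_ID, pos = pos)
  mapped <- map_variant_to_genes(variants[has_coord, , drop = FALSE], gene_intervals)
  # fall back to MAPPED_GENE for rows without usable coordinates
  fb_rows <- which(!has_coord & !is.na(cat_raw$MAPPED_GENE))
  fb <- tibble::tibble(
    variant_id = paste0("row", fb_rows),
    gene_id = suppressWarnings(as.integer(cat_raw$MAPPED_GENE[fb_rows])),
    distance = NA_integer_
  )
  fb <- fb[!is.na(fb$gene_id), , drop = FALSE]
  mapped <- dplyr::bind_rows(mapped, fb)
  if (nrow(mapped) == 0L) {
    return(tibble::tibble(variant_id = character(), gene_id = integer(),
                          trait_id = character(), p_value = numeric(),
                          odds_ratio = numeric(), or_ci_lower = numeric(),
                          pub_date = as.Date(character()), year = integer(),
                          journal = character()))
  }
  row_idx <- as.integer(sub("^row", "", mapped$variant_id))
  tibble::tibble(
    variant_id = cat_raw$SNPS[row_idx],
    gene_id = mapped$gene_id,
    trait_id = trait_id[row_idx],
    p_value = p[row_idx],
    odds_ratio = odds_ratio[row_idx],
    or_ci_lower = or_ci_lower[row_idx],
    pub_date = pub_date[row_idx],
    year = as.integer(format(pub_date[row_idx], "%Y")),
    journal = if ("JOURNAL" %in% names(cat_raw)) cat_raw$JOURNAL[row_idx] else NA_character_
  )
}

# "[1.10-1.30]" -> lower/upper; text after the bracket (units) flags a beta
parse_ci_text <- function(x) {
  x <- ifelse(is.na(x), "", x)
  m <- regmatches(x, regexec("\\[\\s*([0-9.eE+-]+)\\s*-\\s*([0-9.eE+-]+)\\s*\\](.*)$", x))
  lower <- vapply(m, function(g) {
    if (length(g) >= 2) suppressWarnings(as.numeric(g[2])) else NA_real_
  }, numeric(1))
  upper <- vapply(m, function(g) {
    if (length(g) >= 3) suppressWarnings(as.numeric(g[3])) else NA_real_
  }, numeric(1))
  trailing <- vapply(m, function(g) {
    if (length(g) >= 4) trimws(g[4]) else ""
  }, character(1))
  list(lower = lower, upper = upper,
       has_unit = nzchar(trailing) | (is.na(lower) & nzchar(x)))
}

#' Classify genes by their disease associations
#'
#' Combines the OMIM-derived gene-trait kinds with the disease-filtered GWAS
#' associations into a four-way label per gene:
#' \describe{
#'   \item{mendelian}{OMIM Mendelian only, never complex (OMIM or GWAS)}
#'   \item{complex}{complex via OMIM-multifactorial-only or via GWAS, and
#'     not OMIM Mendelian}
#'   \item{both}{OMIM Mendelian and complex (OMIM multifactorial or GWAS)}
#'   \item{none}{no disease association}
#' }
#' For GWAS genes the year of the earliest surviving association is kept,
#' together with the p-value and odds ratio of the strongest (smallest-p)
#' association in that first year.
#'
#' @param omim tibble `gene_id`, `trait_kind` from [parse_omim_genemap()]
#' @param associations disease-filtered association tibble with `gene_id`,
#'   `year`, `p_value`, `odds_ratio`
#' @param gene_universe integer vector of all gene ids (labels cover it)
#' @return tibble `gene_id`, `label`, `first_gwas_year`, `first_assoc_p`,
#'   `first_assoc_or`; one row per universe gene.
#' @export
classify_genes <- function(omim, associations, gene_universe) {
  gene_universe <- sort(unique(as.integer(gene_universe)))
  mend <- unique(omim$gene_id[omim$trait_kind == "mendelian"])
  comp_omim <- unique(omim$gene_id[omim$trait_kind == "complex_multifactorial"])
  gwas <- dplyr::summarise(
    dplyr::group_by(associations, .data$gene_id),
    first_gwas_year = min(.data$year),
    .groups = "drop"
  )
  first_assoc <- dplyr::inner_join(associations, gwas, by = "gene_id")
  first_assoc <- first_assoc[first_assoc$year == first_assoc$first_gwas_year, , drop = FALSE]
  first_assoc <- dplyr::slice_min(dplyr::group_by(first_assoc, .data$gene_id),
                                  order_by = .data$p_value, n = 1L, with_ties = FALSE)
  first_assoc <- dplyr::ungroup(first_assoc)

  is_mend <- gene_universe %in% mend
  is_complex <- gene_universe %in% comp_omim | gene_universe %in% gwas$gene_id
  label <- dplyr::case_when(
    is_mend & is_complex ~ "both",
    is_mend ~ "mendelian",
    is_complex ~ "complex",
    TRUE ~ "none"
  )
  out <- tibble::tibble(gene_id = gene_universe, label = label)
  out <- dplyr::left_join(out, gwas, by = "gene_id")
  out <- dplyr::left_join(
    out,
    dplyr::select(first_assoc, "gene_id", first_assoc_p = "p_value",
                  first_assoc_or = "odds_ratio"),
    by = "gene_id"
  )
  out
}

#' Build per-gene publication histories
#'
#' Tabulates dated gene-publication links into annual counts over
#' `year_range` for every gene in the universe (zero rows included).
#' Publications from before the first year are folded into the per-gene
#' cumulative baseline rather than discarded, so cumulative sums are exact
#' even though those years are outside the likelihood window.
#'
#' @param links tibble `gene_id`, `pmid`, `year` from [assign_pub_years()]
#' @param gene_universe integer vector of all gene ids
#' @param year_range integer length-2, first and last year (default
#'   1950-2015, the rate-model fitting window)
#' @return a [pub_history()] over the universe
#' @export
build_histories <- function(links, gene_universe, year_range = c(1950L, 2015L)) {
  gene_universe <- sort(unique(as.integer(gene_universe)))
  years <- seq.int(year_range[1], year_range[2])
  in_univ <- links$gene_id %in% gene_universe
  if (any(!in_univ)) {
    warning(sum(!in_univ), " link(s) to genes outside the universe dropped")
  }
  links <- links[in_univ, , drop = FALSE]
  after <- links$year > year_range[2]
  links <- links[!after, , drop = FALSE]
  pre <- links$year < year_range[1]

  gfac <- factor(links$gene_id, levels = gene_universe)
  counts <- table(gfac[!pre],
                  factor(links$year[!pre], levels = years))
  counts <- matrix(as.integer(counts), nrow = length(gene_universe),
                   dimnames = list(gene_universe, years))
  baseline <- as.numeric(table(gfac[pre]))
  pub_history(counts, years, baseline)
}

#' Ingest a complete input bundle
#'
#' End-to-end reader: publication links with years, OMIM-style gene-disease
#' map, disease-filtered GWAS catalog, gene universe -> histories, gene
#' classes and association records, plus a filter-accounting report.
#'
#' @param gene2pubmed,years,omim,gwas,efo_terms,genes file paths (see the
#'   individual parsers for dialects)
#' @param taxon NCBI taxon id, default human
#' @param year_range history span, default 1950-2015
#' @param p_max catalog inclusion p-value threshold
#' @return list with `histories`, `classes`, `associations`, `links`,
#'   `gene_info`, `accounting`
#' @export
ingest_bundle <- function(gene2pubmed, years, omim, gwas, efo_terms, genes,
                          taxon = 9606L, year_range = c(1950L, 2015L),
                          p_max = 1e-5) {
  gene_info <- read_gene_info(genes)
  links <- parse_gene2pubmed(gene2pubmed, taxon = taxon)
  links <- assign_pub_years(links, read_year_table(years))
  omim_tab <- parse_omim_genemap(omim)
  efo <- read_efo_terms(efo_terms)
  assoc <- parse_gwas_catalog(gwas, gene_info, p_max = p_max)
  n_assoc_all <- nrow(assoc)
  assoc <- filter_disease_traits(assoc, efo)
  classes <- classify_genes(omim_tab, assoc, gene_info$gene_id)
  histories <- build_histories(links, gene_info$gene_id, year_range)
  acc <- c(attr(links, "accounting"),
           assoc_parsed = n_assoc_all,
           assoc_nondisease = n_assoc_all - nrow(assoc),
           assoc_disease = nrow(assoc))
  list(histories = histories, classes = classes, associations = assoc,
       links = links, gene_info = gene_info, accounting = acc)
}
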