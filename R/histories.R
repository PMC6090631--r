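#' Per-gene annual publication histories
#'
#' A `pub_history` holds, for a fixed gene universe and a contiguous span of
#' calendar years, the number of publications linked to each gene in each
#' year, plus a per-gene baseline of publications that appeared before the
#' first year of the span. The cumulative count for gene *i* through year *t*,
#' written \eqn{P_{i,t}}, is the baseline plus the running sum of annual
#' counts; the cross-gene average of the cumulative counts, \eqn{P^*_t},
#' drives the cohort term of the publication-rate model.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids) and
#'   years in columns (colnames = calendar years), annual publication counts.
#' @param years integer vector of calendar years; defaults to the column
#'   names of `counts`.
#' @param baseline numeric vector of per-gene publication counts from before
#'   `years[1]`, folded into every cumulative sum. A scalar is recycled.
#'
#' @return An object of class `pub_history` with elements `counts`, `years`
#'   and `baseline`.
#' @export
pub_history <- function(counts, years = as.integer(colnames(counts)),
                        baseline = 0) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("`counts` must have gene ids as rownames")
  }
  years <- as.integer(years)
  if (length(years) != ncol(counts)) {
    stop("`years` must have one entry per column of `counts`")
  }
  if (any(diff(years) != 1L)) stop("`years` must be contiguous and ascending")
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("publication counts must be finite and non-negative")
  }
  baseline <- rep_len(as.numeric(baseline), nrow(counts))
  names(baseline) <- rownames(counts)
  colnames(counts) <- years
  structure(list(counts = counts, years = years, baseline = baseline),
            class = "pub_history")
}

#' @export
print.pub_history <- function(x, ...) {
  cat(sprintf("<pub_history> %d genes x years %d-%d; %s publications (+%s pre-%d)\n",
              nrow(x$counts), x$years[1], x$years[length(x$years)],
              format(sum(x$counts), big.mark = ","),
              format(sum(x$baseline), big.mark = ","), x$years[1]))
  invisible(x)
}

#' @export
genes.pub_history <- function(x) rownames(x$counts)

#' Gene identifiers of a history set
#' @param x a `pub_history`
#' @return character vector of gene ids
#' @export
genes <- function(x) UseMethod("genes")

#' Cumulative publication matrix
#'
#' @param h a `pub_history`
#' @return numeric matrix of \eqn{P_{i,t}}: baseline plus running row sums,
#'   same dimnames as `h$counts`. Non-decreasing along every row.
#' @export
cum_matrix <- function(h) {
  stopifnot(inherits(h, "pub_history"))
  cm <- h$counts
  if (ncol(cm) > 1L) {
    cm <- t(apply(cm, 1L, cumsum))
  }
  cm + h$baseline
}

#' Cumulative publications through a given year
#'
#' @param h a `pub_history`
#' @param year calendar year `t`; `cum_at(h, year)` is \eqn{P_{i,t}}. Years
#'   before the span return the baseline alone.
#' @return named numeric vector over genes
#' @export
cum_at <- function(h, year) {
  stopifnot(inherits(h, "pub_history"))
  if (year < h$years[1]) return(h$baseline)
  keep <- h$years <= year
  h$baseline + rowSums(h$counts[, keep, drop = FALSE])
}

#' Cohort mean cumulative publications \eqn{P^*_t}
#'
#' The average cumulative number of publications over all genes in the
#' universe, per year. Includes zero-publication genes: the universe is the
#' full row set of `h`.
#'
#' @param h a `pub_history`
#' @return named numeric vector, one entry per year of `h`, non-decreasing.
#' @export
cohort_means <- function(h) {
  stopifnot(inherits(h, "pub_history"))
  out <- colMeans(cum_matrix(h))
  names(out) <- h$years
  out
}

#' Publications in a window of years
#'
#' Sum of annual counts over `[from, to]` for every gene; years outside the
#' span of `h` contribute nothing (the baseline is not a window).
#'
#' @param h a `pub_history`
#' @param from,to first and last calendar year of the window, inclusive
#' @return named numeric vector over genes
#' @export
window_counts <- function(h, from, to) {
  stopifnot(inherits(h, "pub_history"), from <= to)
  keep <- h$years >= from & h$years <= to
  rowSums(h$counts[, keep, drop = FALSE])
}

#' Subset a history set by gene
#' @param h a `pub_history`
#' @param gene_ids character or integer vector of gene ids to keep
#' @return a `pub_history` over the requested genes, original order of `gene_ids`
#' @export
subset_genes <- function(h, gene_ids) {
  gene_ids <- as.character(gene_ids)
  missing <- setdiff(gene_ids, rownames(h$counts))
  if (length(missing)) {
    stop("genes absent from histories: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  pub_history(h$counts[gene_ids, , drop = FALSE], h$years, h$baseline[gene_ids])
}
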