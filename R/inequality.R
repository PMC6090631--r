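#' Gini coefficient of publication counts
#'
#' Population Gini coefficient of a non-negative count vector:
#' \deqn{G = \sum_{i,j} |x_i - x_j| / (2 n^2 \bar x),}
#' ranging from 0 (perfectly even) to (n-1)/n (one gene holds everything).
#' Computed via the equivalent sorted form
#' \eqn{G = 2 \sum_i i\,x_{(i)} / (n \sum_i x_i) - (n+1)/n}, which is
#' O(n log n). Zero-count genes are included by default; the biased
#' (denominator \eqn{n^2}) population convention is used throughout.
#'
#' @param counts non-negative numeric vector with at least one positive entry
#' @param include_zeros if `FALSE`, drop zero counts first
#' @return Gini coefficient in [0, 1]
#' @export
gini <- function(counts, include_zeros = TRUE) {
  if (!include_zeros) counts <- counts[counts > 0]
  if (length(counts) == 0L || any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (sum(counts) == 0) stop("all counts are zero; Gini undefined")
  x <- sort(counts)
  n <- length(x)
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

#' Lorenz curve of publication counts
#'
#' Cumulative share of publications held by the bottom fraction of genes,
#' genes sorted ascending by count. The curve starts at (0, 0) and ends at
#' (1, 1); the further it sags below the diagonal, the more uneven the
#' distribution. The trapezoid-area Gini derived from this curve agrees
#' with [gini()] to within 1/n.
#'
#' @param counts as in [gini()]
#' @param include_zeros as in [gini()]
#' @return list of class `lorenz_curve` with `ranks` (0 to 1, length n+1),
#'   `cum_share` (0 to 1, length n+1) and `gini_area`, the area-based Gini.
#' @export
lorenz <- function(counts, include_zeros = TRUE) {
  if (!include_zeros) counts <- counts[counts > 0]
  if (length(counts) == 0L || any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  if (sum(counts) == 0) stop("all counts are zero; Lorenz curve undefined")
  x <- sort(counts)
  n <- length(x)
  ranks <- seq.int(0, n) / n
  cum_share <- c(0, cumsum(x) / sum(x))
  # area under the curve by trapezoids; G = 1 - 2 * area
  area <- sum((cum_share[-1] + cum_share[-(n + 1)]) / 2) / n
  structure(list(ranks = ranks, cum_share = cum_share,
                 gini_area = 1 - 2 * area),
            class = "lorenz_curve")
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat(sprintf("<lorenz_curve> n = %d, area Gini = %.4f\n",
              length(x$ranks) - 1L, x$gini_area))
  invisible(x)
}

#' Split publication counts into pre- and post-GWAS eras
#'
#' Totals each gene's publications before the cutoff year and from the
#' cutoff onward. 2005, the year of the first GWAS-catalog entry, is the
#' default boundary; 2007 and 2009 are the conventional alternates and do
#' not change the qualitative picture.
#'
#' @param histories a [pub_history()]
#' @param cutoff_year first year of the post era (default 2005)
#' @return tibble `gene_id`, `pre`, `post`; `pre + post` equals each gene's
#'   in-span total (the pre-span baseline is not included).
#' @export
era_split <- function(histories, cutoff_year = 2005L) {
  stopifnot(inherits(histories, "pub_history"))
  pre_cols <- histories$years < cutoff_year
  tibble::tibble(
    gene_id = as.integer(rownames(histories$counts)),
    pre = unname(rowSums(histories$counts[, pre_cols, drop = FALSE])),
    post = unname(rowSums(histories$counts[, !pre_cols, drop = FALSE]))
  )
}

#' Publication ranks by disease class
#'
#' Ranks all genes ascending by publication count (rank 1 = fewest
#' publications, rank n = most), breaking count ties toward the smaller
#' gene id, and returns each gene's rank with its disease-class label.
#' Distributions are not normalized across classes.
#'
#' @param counts named numeric vector of per-gene counts (names = gene ids)
#' @param classes tibble `gene_id`, `label` from [classify_genes()]
#' @return tibble `gene_id`, `count`, `rank`, `label`
#' @export
rank_distribution <- function(counts, classes) {
  gene_id <- as.integer(names(counts))
  ord <- order(counts, gene_id)
  rank <- integer(length(counts))
  rank[ord] <- seq_along(counts)
  out <- tibble::tibble(gene_id = gene_id, count = as.numeric(counts), rank = rank)
  dplyr::left_join(out, dplyr::select(classes, "gene_id", "label"), by = "gene_id")
}

#' Era shift in publication ranks of a disease class
#'
#' Tests whether the publication ranks of a class of genes (complex-disease
#' genes by default) differ between the pre- and post-GWAS eras. Ranks are
#' computed within the full gene universe for each era separately, then
#' restricted to the tested class, and compared with a two-sided
#' Mann-Whitney U test.
#'
#' @param pre_counts,post_counts named per-gene count vectors over the same
#'   universe (e.g. the `pre`/`post` columns of [era_split()])
#' @param classes tibble `gene_id`, `label`
#' @param class_filter label(s) to test, default `"complex"`
#' @return list `U`, `p`, `n`, plus the two rank vectors
#' @export
rank_shift_test <- function(pre_counts, post_counts, classes,
                            class_filter = "complex") {
  stopifnot(length(pre_counts) == length(post_counts))
  pre_rd <- rank_distribution(pre_counts, classes)
  post_rd <- rank_distribution(post_counts, classes)
  keep <- pre_rd$label %in% class_filter
  r1 <- pre_rd$rank[keep]
  r2 <- post_rd$rank[keep]
  if (length(r1) < 2L) stop("fewer than 2 genes in the tested class")
  wt <- stats::wilcox.test(r1, r2, alternative = "two.sided",
                           exact = FALSE, correct = FALSE)
  list(U = unname(wt$statistic), p = wt$p.value, n = length(r1),
       pre_ranks = r1, post_ranks = r2)
}
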