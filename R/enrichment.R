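#' Fisher's exact term enrichment of a gene set
#'
#' For every ontology term, builds the 2x2 table of (in set / out of set) x
#' (annotated / not annotated) over the analysis universe and computes the
#' hypergeometric Fisher p-value for the chosen tail plus the sample odds
#' ratio. Terms annotating no gene in the universe are skipped.
#'
#' @param gene_set Gene identifiers (must lie within `universe`).
#' @param annotation A `phenotype_annotation` (ancestor-closed).
#' @param universe Gene identifiers defining the background; default all
#'   genes of the annotation.
#' @param tail "greater" (over-representation, default) or "two_sided".
#' @param namespace Label stored with every result row (e.g. an ontology
#'   aspect); used by [fdr_adjust()] to group the FDR correction.
#' @return Tibble with term_id, namespace, the four table counts
#'   (`a_in_set` = in set & annotated, etc.), odds_ratio and p.
#' @export
fisher_enrichment <- function(gene_set, annotation, universe = NULL,
                              tail = c("greater", "two_sided"),
                              namespace = "phenotype") {
  tail <- match.arg(tail)
  stopifnot(inherits(annotation, "phenotype_annotation"))
  if (is.null(universe)) universe <- annotation$gene_ids
  universe <- intersect(universe, annotation$gene_ids)
  bad <- setdiff(gene_set, universe)
  if (length(bad)) {
    stop(sprintf("%d gene_set members are outside the universe (e.g. '%s')",
                 length(bad), bad[1L]), call. = FALSE)
  }
  m <- annotation$matrix[universe, , drop = FALSE]
  in_set <- universe %in% gene_set
  n_set <- sum(in_set)
  n_univ <- length(universe)
  ann_total <- Matrix::colSums(m)
  keep <- ann_total > 0
  n_skip <- sum(!keep)
  if (n_skip > 0L) message(sprintf("%d terms with no annotated genes in universe skipped", n_skip))
  m <- m[, keep, drop = FALSE]
  ann_total <- ann_total[keep]
  a <- as.numeric(Matrix::colSums(m[in_set, , drop = FALSE]))   # in set, annotated
  b <- n_set - a                                                # in set, not annotated
  c_ <- ann_total - a                                           # out of set, annotated
  d <- n_univ - n_set - c_                                      # out of set, not annotated
  p <- vapply(seq_along(a), function(i) {
    hyper_tail_p(a[i], ann_total[i], n_univ, n_set, tail)
  }, 0.0)
  or <- (a * d) / (b * c_)
  tibble::tibble(
    term_id = colnames(m), namespace = namespace,
    a_in_set = a, b_in_set = b, a_out_set = c_, b_out_set = d,
    odds_ratio = or, p = pmin(1, p)
  )
}

# P for a 2x2 table under the hypergeometric null: a annotated genes in a
# draw of n_set from a universe with K annotated genes.
hyper_tail_p <- function(a, K, N, n_set, tail) {
  if (tail == "greater") {
    stats::phyper(a - 1, K, N - K, n_set, lower.tail = FALSE)
  } else {
    support <- max(0, n_set - (N - K)):min(K, n_set)
    dens <- stats::dhyper(support, K, N - K, n_set)
    sum(dens[dens <= stats::dhyper(a, K, N - K, n_set) * (1 + 1e-7)])
  }
}

#' Benjamini-Hochberg adjustment within namespaces
#'
#' Applies the FDR step-up correction independently within each namespace
#' (e.g. per ontology aspect), appending a `q` column.
#'
#' @param results Tibble from [fisher_enrichment()] (or any tibble with `p`
#'   and the grouping column).
#' @param group_by Column name holding the namespace.
#' @return `results` with a `q` column, sorted by q then p.
#' @export
fdr_adjust <- function(results, group_by = "namespace") {
  stopifnot("p" %in% names(results), group_by %in% names(results))
  results$q <- NA_real_
  for (ns in unique(results[[group_by]])) {
    idx <- results[[group_by]] == ns
    results$q[idx] <- stats::p.adjust(results$p[idx], method = "BH")
  }
  results[order(results$q, results$p), ]
}
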