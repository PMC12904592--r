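#' Per-cell expressed-gene fraction and component contribution
#'
#' For one latent phenotype component, computes per cell (i) the fraction of
#' analysed genes active in the cell and (ii) the summed W weights of those
#' active genes for the component, optionally normalized by the component's
#' total W mass (its "relative contribution").
#'
#' @param active Binary cells x genes matrix.
#' @param model An `nmf_model`; genes are aligned by name with `active`'s
#'   columns.
#' @param component Component index or name.
#' @param normalize Divide by the component's total W mass (default TRUE).
#' @param cell_type Optional per-cell type labels to carry along.
#' @return Tibble with `cell_id`, `cell_type`, `expressed_fraction`,
#'   `component_weight`.
#' @export
cell_contributions <- function(active, model, component, normalize = TRUE,
                               cell_type = NULL) {
  stopifnot(inherits(model, "nmf_model"))
  genes <- intersect(colnames(active), rownames(model$W))
  if (length(genes) == 0L) stop("no genes shared between activity matrix and model", call. = FALSE)
  if (is.character(component)) component <- match(component, colnames(model$W))
  act <- active[, genes, drop = FALSE]
  w <- model$W[genes, component]
  total <- sum(w)
  if (normalize && total == 0) {
    stop("component has zero total W mass; cannot normalize", call. = FALSE)
  }
  weight <- as.numeric(act %*% w)
  if (normalize) weight <- weight / total
  tibble::tibble(
    cell_id = if (is.null(rownames(active))) as.character(seq_len(nrow(active))) else rownames(active),
    cell_type = if (is.null(cell_type)) NA_character_ else as.character(cell_type),
    expressed_fraction = as.numeric(Matrix::rowSums(act)) / length(genes),
    component_weight = weight
  )
}

#' Residuals of component contribution regressed on expressed fraction
#'
#' Ordinary least-squares line of `component_weight` on
#' `expressed_fraction` over all cells; residual = observed - predicted, so
#' positive residuals mean the cell's expressed genes contribute more to
#' the component than its overall expression breadth predicts.
#'
#' @param contribs Tibble from [cell_contributions()].
#' @return `contribs` with `predicted` and `residual` columns.
#' @export
regression_residuals <- function(contribs) {
  x <- contribs$expressed_fraction
  y <- contribs$component_weight
  if (length(unique(x)) < 3L) {
    stop("need at least 3 cells with distinct expressed fractions", call. = FALSE)
  }
  if (stats::var(x) == 0) stop("expressed fractions have zero variance", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  contribs$predicted <- y - fit$residuals
  contribs$residual <- fit$residuals
  contribs
}

#' One-sided two-sample Kolmogorov-Smirnov statistic
#'
#' The statistic is `sup_x [ECDF_rest(x) - ECDF_focal(x)]` clipped at 0, so
#' it is large when the focal sample is stochastically larger than the rest
#' (its ECDF lags behind). It lies in [0, 1]: 0 for identical samples, 1
#' for complete separation with the focal sample on top. The p-value uses
#' the one-sided two-sample asymptotic formula
#' `exp(-2 d^2 m n / (m + n))`.
#'
#' @param focal,rest Numeric samples (nonempty).
#' @return List with `statistic`, `p_value`, sample sizes and an
#'   `unreliable` flag (focal size < 2).
#' @export
ks_one_sided <- function(focal, rest) {
  focal <- focal[!is.na(focal)]
  rest <- rest[!is.na(rest)]
  m <- length(focal); n <- length(rest)
  if (m == 0L || n == 0L) stop("both samples must be nonempty", call. = FALSE)
  jumps <- sort(unique(c(focal, rest)))
  cdf_f <- vapply(jumps, function(t) mean(focal <= t), 0.0)
  cdf_r <- vapply(jumps, function(t) mean(rest <= t), 0.0)
  d <- max(0, max(cdf_r - cdf_f))
  p <- exp(-2 * d^2 * m * n / (m + n))
  list(statistic = d, p_value = min(1, p), n_focal = m, n_rest = n,
       unreliable = m < 2L)
}

#' Scan all (cell type, component) pairs for mediator associations
#'
#' For every latent component: per-cell contributions are computed over all
#' cells and regressed on expressed fraction; for every cell type with more
#' than `min_cells` labeled cells, the one-sided KS statistic compares the
#' focal type's residuals against all remaining cells. Large significant
#' statistics flag the type as a mediator of the component.
#'
#' @param active Binary cells x genes matrix.
#' @param model An `nmf_model`.
#' @param cell_types Character vector of per-cell type labels (NA allowed;
#'   unlabeled cells join the regression and the "rest" sample only).
#' @param min_cells Only types with strictly more than this many cells are
#'   tested (default 50).
#' @param alpha Significance cutoff for the p matrix (default 1e-4); no
#'   multiple-testing correction is applied, but the raw test count is
#'   recorded.
#' @param normalize Passed to [cell_contributions()].
#' @return A `mediator_result`: `ks_matrix` and `p_matrix` (cell types x
#'   components), logical `significant`, `alpha`, `n_tests` and per-type
#'   cell counts.
#' @export
mediator_scan <- function(active, model, cell_types, min_cells = 50L,
                          alpha = 1e-4, normalize = TRUE) {
  stopifnot(inherits(model, "nmf_model"), nrow(active) == length(cell_types))
  counts <- table(cell_types[!is.na(cell_types)])
  eligible <- sort(names(counts)[counts > min_cells])
  if (length(eligible) == 0L) {
    stop(sprintf("no cell type has more than %d cells", min_cells), call. = FALSE)
  }
  comps <- colnames(model$W)
  ks <- matrix(NA_real_, length(eligible), length(comps),
               dimnames = list(eligible, comps))
  pv <- ks
  for (j in seq_along(comps)) {
    contribs <- cell_contributions(active, model, j, normalize = normalize,
                                   cell_type = cell_types)
    res <- regression_residuals(contribs)$residual
    for (i in seq_along(eligible)) {
      foc <- !is.na(cell_types) & cell_types == eligible[i]
      kk <- ks_one_sided(res[foc], res[!foc])
      ks[i, j] <- kk$statistic
      pv[i, j] <- kk$p_value
    }
  }
  structure(
    list(ks_matrix = ks, p_matrix = pv, significant = pv < alpha,
         alpha = alpha, n_tests = length(ks),
         cell_type_counts = counts[eligible], min_cells = as.integer(min_cells),
         normalize = normalize),
    class = "mediator_result"
  )
}

#' @export
print.mediator_result <- function(x, ...) {
  cat(sprintf("<mediator_result> %d cell types x %d components; %d significant at p < %g (of %d tests)\n",
              nrow(x$ks_matrix), ncol(x$ks_matrix), sum(x$significant),
              x$alpha, x$n_tests))
  invisible(x)
}

#' Tidy a mediator scan into long format
#'
#' @param x A `mediator_result`.
#' @param ... Unused.
#' @export
tidy.mediator_result <- function(x, ...) {
  tibble::tibble(
    cell_type = rep(rownames(x$ks_matrix), times = ncol(x$ks_matrix)),
    component = rep(colnames(x$ks_matrix), each = nrow(x$ks_matrix)),
    ks = as.vector(x$ks_matrix),
    p_value = as.vector(x$p_matrix),
    significant = as.vector(x$significant)
  )
}

#' @export
glance.mediator_result <- function(x, ...) {
  tibble::tibble(
    n_cell_types = nrow(x$ks_matrix), n_components = ncol(x$ks_matrix),
    n_tests = x$n_tests, n_significant = sum(x$significant), alpha = x$alpha
  )
}

#' Hierarchically cluster the mediator KS matrix
#'
#' Non-significant entries are zeroed, then rows (cell types) and columns
#' (components) are clustered by agglomerative clustering. Dendrograms are
#' exported as Newick strings.
#'
#' @param result A `mediator_result`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric Distance metric for [stats::dist()].
#' @return List with `row_order`, `col_order` (leaf label sequences),
#'   `row_newick`, `col_newick` (NULL for single rows/columns) and the
#'   masked, reordered `matrix`.
#' @export
cluster_heatmap <- function(result, linkage = "average", metric = "euclidean") {
  stopifnot(inherits(result, "mediator_result"))
  m <- result$ks_matrix
  m[!result$significant] <- 0
  cluster_axis <- function(mat) {
    if (nrow(mat) < 2L) {
      return(list(order = rownames(mat), newick = NULL))
    }
    hc <- stats::hclust(stats::dist(mat, method = metric), method = linkage)
    nwk <- ape::write.tree(ape::as.phylo(hc))
    list(order = hc$labels[hc$order], newick = nwk)
  }
  rows <- cluster_axis(m)
  cols <- cluster_axis(t(m))
  list(row_order = rows$order, col_order = cols$order,
       row_newick = rows$newick, col_newick = cols$newick,
       matrix = m[rows$order, cols$order, drop = FALSE])
}
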