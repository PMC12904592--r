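#' Cosine similarity of two vectors
#'
#' `sim(u, v) = (u . v) / (||u|| ||v||)`; two proportional vectors have
#' similarity 1, and non-negative inputs give values in [0, 1]. A zero
#' vector has undefined similarity and yields `NA`.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single numeric value (or `NA` for zero input).
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' All-pairs cosine similarity between gene signature rows
#'
#' @param mat Numeric matrix, genes x features.
#' @return Symmetric genes x genes matrix; the diagonal is 1 for nonzero
#'   rows, and zero rows give `NA` rows/columns.
#' @export
pairwise_similarity <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 genes", call. = FALSE)
  nrm <- sqrt(rowSums(mat^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  scaled <- mat / nrm
  sim <- tcrossprod(scaled)
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  diag(sim) <- 1
  sim[zero, ] <- NA_real_
  sim[, zero] <- NA_real_
  dimnames(sim) <- list(rownames(mat), rownames(mat))
  sim
}

#' Per-gene median similarity
#'
#' The median of a gene's off-diagonal similarities (the self-pair is
#' excluded so a guaranteed 1 cannot inflate every gene); missing entries
#' are ignored.
#'
#' @param sim Square symmetric similarity matrix.
#' @return Named numeric vector of medians (NA when all pairs are missing).
#' @export
median_similarity <- function(sim) {
  stopifnot(nrow(sim) == ncol(sim))
  n <- nrow(sim)
  out <- vapply(seq_len(n), function(i) {
    v <- sim[i, -i]
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  }, 0.0)
  names(out) <- rownames(sim)
  out
}

#' Per-gene similarity profiles across the two spaces
#'
#' Computes each gene's median pairwise cosine similarity in the
#' developmental space (rows of the developmental matrix) and in the
#' phenotypic space (rows of the NMF feature matrix W), over the genes
#' present in both spaces.
#'
#' @param dev A `dev_matrix`.
#' @param model An `nmf_model`.
#' @return Tibble with `gene_id`, `median_simD`, `median_simP`.
#' @export
similarity_profiles <- function(dev, model) {
  stopifnot(inherits(dev, "dev_matrix"), inherits(model, "nmf_model"))
  genes <- intersect(rownames(dev$values), rownames(model$W))
  if (length(genes) < 2L) stop("fewer than 2 genes shared between spaces", call. = FALSE)
  simD <- median_similarity(pairwise_similarity(dev$values[genes, , drop = FALSE]))
  simP <- median_similarity(pairwise_similarity(model$W[genes, , drop = FALSE]))
  tibble::tibble(gene_id = genes,
                 median_simD = unname(simD),
                 median_simP = unname(simP))
}

#' Sliding-window trend of phenotypic vs developmental similarity
#'
#' Genes are sorted by ascending `median_simD`; each contiguous window of
#' `window` genes (step 1) contributes its mean `median_simD` and mean
#' `median_simP`, tracing the rule's trend line.
#'
#' @param profiles Tibble with `median_simD` and `median_simP`.
#' @param window Window size (<= number of genes with complete medians).
#' @return Tibble with `window_start`, `mean_simD`, `mean_simP`; length
#'   `n - window + 1`.
#' @export
sliding_window_trend <- function(profiles, window = 100L) {
  df <- profiles[stats::complete.cases(profiles[, c("median_simD", "median_simP")]), ]
  n <- nrow(df)
  if (window > n) stop("window exceeds the number of genes", call. = FALSE)
  df <- df[order(df$median_simD), ]
  cd <- cumsum(df$median_simD)
  cp <- cumsum(df$median_simP)
  idx <- seq_len(n - window + 1L)
  hi <- idx + window - 1L
  sum_d <- cd[hi] - c(0, cd)[idx]
  sum_p <- cp[hi] - c(0, cp)[idx]
  tibble::tibble(window_start = idx,
                 mean_simD = sum_d / window,
                 mean_simP = sum_p / window)
}

#' Percentile-class contingency between the two similarity spaces
#'
#' Genes are binned independently into percentile classes of `median_simD`
#' and `median_simP` (default quintiles); entry (p, d) is the fraction of
#' genes in developmental class d that fall in phenotypic class p, so each
#' column sums to 1.
#'
#' @param profiles Tibble with `median_simD` and `median_simP`.
#' @param edges Ascending percentile boundaries inside (0, 100).
#' @return A `quintile_contingency` object: column-stochastic `matrix`
#'   (phenotypic class x developmental class), `class_edges` and per-class
#'   gene counts.
#' @export
quintile_contingency <- function(profiles, edges = c(20, 40, 60, 80)) {
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= 100)) {
    stop("edges must be ascending percentiles inside (0, 100)", call. = FALSE)
  }
  df <- profiles[stats::complete.cases(profiles[, c("median_simD", "median_simP")]), ]
  probs <- c(0, edges / 100, 1)
  bin_of <- function(x) {
    q <- stats::quantile(x, probs, names = FALSE)
    q[1L] <- -Inf; q[length(q)] <- Inf
    if (anyDuplicated(q)) {
      # heavy ties collapse quantile breaks; bin by percent rank instead
      pr <- (rank(x, ties.method = "average") - 0.5) / length(x) * 100
      return(findInterval(pr, edges) + 1L)
    }
    cut(x, breaks = q, labels = FALSE, right = TRUE)
  }
  d_class <- bin_of(df$median_simD)
  p_class <- bin_of(df$median_simP)
  k <- length(probs) - 1L
  counts <- matrix(0, k, k)
  for (i in seq_len(nrow(df))) {
    counts[p_class[i], d_class[i]] <- counts[p_class[i], d_class[i]] + 1
  }
  col_n <- colSums(counts)
  mat <- counts
  for (j in seq_len(k)) {
    if (col_n[j] == 0) {
      warning(sprintf("developmental class %d is empty", j), call. = FALSE)
      mat[, j] <- NA_real_
    } else {
      mat[, j] <- counts[, j] / col_n[j]
    }
  }
  lab <- paste0("p", c(edges, 100))
  dimnames(mat) <- list(phenotypic = lab, developmental = lab)
  structure(list(matrix = mat, class_edges = edges, counts = counts,
                 n_genes = nrow(df)),
            class = "quintile_contingency")
}

#' @export
print.quintile_contingency <- function(x, ...) {
  cat(sprintf("<quintile_contingency> %d genes, classes at percentiles %s\n",
              x$n_genes, paste(x$class_edges, collapse = "/")))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @export
tidy.quintile_contingency <- function(x, ...) {
  tibble::tibble(
    phenotypic_class = rep(rownames(x$matrix), times = ncol(x$matrix)),
    developmental_class = rep(colnames(x$matrix), each = nrow(x$matrix)),
    fraction = as.vector(x$matrix)
  )
}

#' Loess fit of phenotypic on developmental similarity, with residuals
#'
#' Fits a local-linear Loess curve (tricube weights) of `median_simP` on
#' `median_simD` and stores, for each gene, the fitted value and the
#' residual (observed - fitted). The default family `"symmetric"` iterates
#' biweight reweighting so that the genes deviating from the rule -- the
#' ones the residuals are meant to expose -- do not drag the trend toward
#' themselves.
#'
#' @param profiles Tibble with `median_simD` and `median_simP`.
#' @param span Loess span in (0, 1].
#' @param family Loess family, `"symmetric"` (robust, default) or
#'   `"gaussian"`.
#' @return `profiles` with `loess_fit` and `residual` columns added (NA for
#'   genes with missing medians, which are excluded from the fit).
#' @export
loess_fit_residuals <- function(profiles, span = 0.3,
                                family = c("symmetric", "gaussian")) {
  family <- match.arg(family)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  ok <- stats::complete.cases(profiles[, c("median_simD", "median_simP")])
  n <- sum(ok)
  if (n < 10L) stop("need >= 10 genes with non-missing medians", call. = FALSE)
  if (floor(span * n) < 4L) {
    stop(sprintf("span %.3f gives local neighborhoods of < 4 points; minimum usable span is %.3f",
                 span, 4 / n), call. = FALSE)
  }
  df <- profiles[ok, ]
  fit <- stats::loess(median_simP ~ median_simD, data = df, span = span,
                      degree = 1, family = family,
                      control = stats::loess.control(surface = "direct"))
  fitted_vals <- stats::predict(fit, newdata = df)
  profiles$loess_fit <- NA_real_
  profiles$residual <- NA_real_
  profiles$loess_fit[ok] <- fitted_vals
  profiles$residual[ok] <- df$median_simP - fitted_vals
  n_miss <- sum(!ok)
  if (n_miss > 0L) message(sprintf("%d genes with missing medians excluded from fit", n_miss))
  attr(profiles, "loess_span") <- span
  attr(profiles, "loess_family") <- family
  profiles
}

#' Classify genes by adherence to the development-to-phenotype rule
#'
#' Labels each gene by where it sits relative to percentile cutoffs of
#' `median_simD`, `median_simP` and the Loess residual:
#' \describe{
#'   \item{D-P}{high developmental similarity, residual inside the central
#'     band, and high phenotypic similarity -- genes that follow the rule.}
#'   \item{D-p}{high developmental similarity but residual below the lower
#'     residual percentile -- developmental divergence.}
#'   \item{d-P}{low developmental similarity but residual above the upper
#'     residual percentile -- phenotypic degeneracy.}
#'   \item{other}{everything else.}
#' }
#'
#' @param profiles Output of [loess_fit_residuals()].
#' @param simD_hi_pct Percentile defining "high" similarity (applied to
#'   `median_simD`, and to `median_simP` for the D-P class).
#' @param simD_lo_pct Percentile defining "low" developmental similarity.
#' @param resid_pct Percentile width of each residual tail.
#' @return `profiles` with a `rule_class` column; cutoff values are attached
#'   as the `rule_cutoffs` attribute. Genes with missing inputs get `NA`.
#' @export
classify_rule <- function(profiles, simD_hi_pct = 70, simD_lo_pct = 30,
                          resid_pct = 20) {
  stopifnot(all(c("median_simD", "median_simP", "residual") %in% names(profiles)))
  ok <- stats::complete.cases(profiles[, c("median_simD", "median_simP", "residual")])
  d <- profiles$median_simD
  p <- profiles$median_simP
  r <- profiles$residual
  d_hi <- stats::quantile(d[ok], simD_hi_pct / 100, names = FALSE)
  d_lo <- stats::quantile(d[ok], simD_lo_pct / 100, names = FALSE)
  p_hi <- stats::quantile(p[ok], simD_hi_pct / 100, names = FALSE)
  r_lo <- stats::quantile(r[ok], resid_pct / 100, names = FALSE)
  r_hi <- stats::quantile(r[ok], 1 - resid_pct / 100, names = FALSE)
  cls <- rep(NA_character_, nrow(profiles))
  cls[ok] <- "other"
  is_DP <- ok & d >= d_hi & r >= r_lo & r <= r_hi & p >= p_hi
  is_Dp <- ok & d >= d_hi & r < r_lo
  is_dP <- ok & d <= d_lo & r > r_hi
  cls[is_DP] <- "D-P"
  cls[is_Dp] <- "D-p"
  cls[is_dP] <- "d-P"
  profiles$rule_class <- cls
  for (lab in c("D-P", "D-p", "d-P")) {
    if (!any(cls == lab, na.rm = TRUE)) {
      message(sprintf("rule class %s is empty", lab))
    }
  }
  attr(profiles, "rule_cutoffs") <- c(simD_hi = d_hi, simD_lo = d_lo,
                                      simP_hi = p_hi, resid_lo = r_lo,
                                      resid_hi = r_hi)
  profiles
}

#' Average developmental and phenotypic "barcode" profiles per rule class
#'
#' For each requested class, the arithmetic mean of the genes' stage
#' profiles (fraction of cell types active per stage) and of their NMF
#' phenotypic vectors (rows of W).
#'
#' @param stage_prof Genes x stages matrix from [stage_profile()].
#' @param model An `nmf_model`.
#' @param labels Tibble with `gene_id` and `rule_class` (e.g. from
#'   [classify_rule()]).
#' @param classes Classes to profile.
#' @return Tibble in long format: `rule_class`, `space` ("stage" or
#'   "component"), `feature`, `mean_value`, `n_genes`.
#' @export
class_barcodes <- function(stage_prof, model, labels,
                           classes = c("D-P", "D-p", "d-P")) {
  stopifnot(inherits(model, "nmf_model"))
  out <- list()
  for (cl in classes) {
    genes <- labels$gene_id[!is.na(labels$rule_class) & labels$rule_class == cl]
    gs <- intersect(genes, rownames(stage_prof))
    gw <- intersect(genes, rownames(model$W))
    if (length(gs) == 0L && length(gw) == 0L) {
      message(sprintf("class %s has no genes; profiles missing", cl))
      next
    }
    if (length(gs)) {
      m <- colMeans(stage_prof[gs, , drop = FALSE], na.rm = TRUE)
      out[[length(out) + 1L]] <- tibble::tibble(
        rule_class = cl, space = "stage", feature = names(m),
        mean_value = unname(m), n_genes = length(gs))
    }
    if (length(gw)) {
      m <- colMeans(model$W[gw, , drop = FALSE])
      out[[length(out) + 1L]] <- tibble::tibble(
        rule_class = cl, space = "component", feature = names(m),
        mean_value = unname(m), n_genes = length(gw))
    }
  }
  dplyr::bind_rows(out)
}
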