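#' Expression breadth per gene
#'
#' Fraction of all retained cells in which each gene is active, regardless
#' of cell type or stage.
#'
#' @param active Binary cells x genes matrix.
#' @return Tibble with `gene_id` and `breadth` in [0, 1].
#' @export
expression_breadth <- function(active) {
  if (nrow(active) < 1L) stop("need at least one retained cell", call. = FALSE)
  tibble::tibble(
    gene_id = colnames(active),
    breadth = as.numeric(Matrix::colSums(active) / nrow(active))
  )
}

#' Resampling null for mean expression breadth of gene sets
#'
#' For each observed gene set, compares its mean breadth against `B` means
#' of random same-size gene sets drawn without replacement from all genes.
#' Empirical p-values use the add-one estimator
#' `(1 + exceedances) / (B + 1)`, so they can never reach zero.
#'
#' @param breadth Tibble from [expression_breadth()] (or a named numeric
#'   vector of per-gene breadths).
#' @param sets Named list of gene-id vectors (e.g. pleiotropic /
#'   non-pleiotropic sets).
#' @param set_size Resample size; default `NULL` uses each observed set's
#'   own size.
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed; results are bit-for-bit reproducible.
#' @return A `breadth_null` object: a `summary` tibble (set, n, observed
#'   mean, p_upper, p_lower) and the per-set `null_means` vectors.
#' @export
breadth_null <- function(breadth, sets, set_size = NULL, B = 1000L, seed = 1L) {
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (is.data.frame(breadth)) {
    b <- stats::setNames(breadth$breadth, breadth$gene_id)
  } else {
    b <- breadth
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  nulls <- list()
  rows <- list()
  for (nm in names(sets)) {
    genes <- intersect(sets[[nm]], names(b))
    n <- if (is.null(set_size)) length(genes) else set_size
    if (n > length(b)) stop("set_size exceeds the number of genes", call. = FALSE)
    obs <- mean(b[genes])
    null_means <- vapply(seq_len(B), function(i) mean(sample(b, n)), 0.0)
    rows[[nm]] <- tibble::tibble(
      set = nm, n = length(genes), resample_n = n, observed_mean = obs,
      p_upper = (1 + sum(null_means >= obs)) / (B + 1),
      p_lower = (1 + sum(null_means <= obs)) / (B + 1)
    )
    nulls[[nm]] <- null_means
  }
  structure(list(summary = dplyr::bind_rows(rows), null_means = nulls,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "breadth_null")
}

#' @export
print.breadth_null <- function(x, ...) {
  cat(sprintf("<breadth_null> B = %d resamples (seed %d)\n", x$B, x$seed))
  print(x$summary)
  invisible(x)
}

#' Stage onset and range of expression per gene
#'
#' @param stage_prof Genes x stages matrix from [stage_profile()], columns
#'   ordered by embryonic time.
#' @param min_fraction A gene counts as expressed at a stage when its
#'   fraction of active cell types exceeds this value (default 0, i.e. at
#'   least one cell type).
#' @return Tibble with `gene_id`, `onset_stage` (1-based index of the first
#'   stage with activity) and `stage_fraction` (fraction of stages with
#'   activity). Both are `NA` for genes inactive at every stage.
#' @export
stage_usage <- function(stage_prof, min_fraction = 0) {
  act <- !is.na(stage_prof) & stage_prof > min_fraction
  n_stages <- ncol(stage_prof)
  onset <- apply(act, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
  frac <- unname(rowSums(act)) / n_stages
  frac[is.na(onset)] <- NA_real_
  tibble::tibble(gene_id = rownames(stage_prof),
                 onset_stage = as.integer(onset),
                 stage_fraction = frac)
}

#' Developmental-coordinate enrichment of a gene set
#'
#' For each coordinate, compares the mean developmental-matrix value over
#' the gene set against `B` random same-size gene sets, summarized as a
#' z-score `(observed - null_mean) / null_sd`. Coordinates with a
#' degenerate null (sd = 0) get z = 0 when the observed mean equals the
#' null mean and `NA` otherwise.
#'
#' @param dev A `dev_matrix`.
#' @param gene_set Gene identifiers (subset of the matrix's genes).
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param top_n How many top coordinates (by z, ties broken by coordinate
#'   label) to flag.
#' @return A tibble (class `coordinate_enrichment`) with one row per
#'   coordinate: observed_mean, null_mean, null_sd, z, rank, top (logical).
#' @export
coordinate_enrichment <- function(dev, gene_set, B = 1000L, seed = 1L,
                                  top_n = 100L) {
  stopifnot(inherits(dev, "dev_matrix"))
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  genes <- rownames(dev$values)
  gene_set <- intersect(gene_set, genes)
  if (length(gene_set) == 0L) stop("gene_set shares no genes with the matrix", call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  obs <- colMeans(dev$values[gene_set, , drop = FALSE])
  n <- length(gene_set)
  null_mat <- matrix(0, B, ncol(dev$values))
  for (i in seq_len(B)) {
    null_mat[i, ] <- colMeans(dev$values[sample(genes, n), , drop = FALSE])
  }
  mu <- colMeans(null_mat)
  sdv <- apply(null_mat, 2L, stats::sd)
  z <- rep(NA_real_, length(obs))
  pos <- sdv > 0
  z[pos] <- (obs[pos] - mu[pos]) / sdv[pos]
  degen_equal <- !pos & abs(obs - mu) < 1e-12
  z[degen_equal] <- 0
  n_degen_na <- sum(!pos & !degen_equal)
  if (n_degen_na > 0L) {
    message(sprintf("%d coordinates have degenerate nulls; z set to NA", n_degen_na))
  }
  coord <- colnames(dev$values)
  ord <- order(-z, coord, na.last = TRUE)
  rank <- integer(length(z))
  rank[ord] <- seq_along(ord)
  out <- tibble::tibble(
    coordinate = coord, observed_mean = unname(obs), null_mean = unname(mu),
    null_sd = unname(sdv), z = unname(z), rank = rank,
    top = rank <= min(top_n, sum(!is.na(z)))
  )
  class(out) <- c("coordinate_enrichment", class(out))
  attr(out, "B") <- as.integer(B)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "set_size") <- n
  out
}

#' Pleiotropy-score distributions per rule class
#'
#' @param pleio A `pleiotropy_result` (from [pleiotropy_scores()]).
#' @param labels Tibble with `gene_id` and `rule_class`.
#' @param classes Classes to summarize.
#' @return A `class_pleiotropy` object: per-class `summary` tibble (n,
#'   median, quartiles) and kernel-density curves for classes with at least
#'   3 genes.
#' @export
pleiotropy_by_class <- function(pleio, labels, classes = c("D-P", "D-p", "d-P")) {
  rows <- list(); dens <- list()
  for (cl in classes) {
    genes <- labels$gene_id[!is.na(labels$rule_class) & labels$rule_class == cl]
    sc <- pleio$score[pleio$gene_id %in% genes]
    if (length(sc) == 0L) next
    qs <- stats::quantile(sc, c(0.25, 0.5, 0.75), names = FALSE)
    rows[[cl]] <- tibble::tibble(rule_class = cl, n = length(sc),
                                 q25 = qs[1L], median = qs[2L], q75 = qs[3L],
                                 mean = mean(sc))
    if (length(sc) >= 3L) {
      d <- stats::density(sc)
      dens[[cl]] <- tibble::tibble(score = d$x, density = d$y)
    }
  }
  structure(list(summary = dplyr::bind_rows(rows), densities = dens),
            class = "class_pleiotropy")
}

#' @export
print.class_pleiotropy <- function(x, ...) {
  cat("<class_pleiotropy>\n")
  print(x$summary)
  invisible(x)
}
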