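#' Non-negative matrix factorization of a phenotype annotation matrix
#'
#' Factorizes the binary gene x term matrix V as V ~ W H with W (genes x k)
#' and H (k x terms) non-negative, minimizing Frobenius loss by
#' multiplicative updates. The first restart is initialized with
#' non-negative double SVD (NNDSVDa); the remaining `n_restarts - 1`
#' restarts use seeded random initializations, and the fit with the smallest
#' reconstruction error is returned. Rows of W are the per-gene phenotypic
#' vectors; H rows describe each latent component over ontology terms.
#'
#' @param annotation A `phenotype_annotation` (see [ancestor_closure()],
#'   [filter_annotation()]) or a non-negative numeric matrix.
#' @param k Factorization rank (number of latent phenotype components).
#' @param seed Integer seed; results are deterministic given
#'   `(seed, n_restarts)`.
#' @param n_restarts Number of initializations (>= 1).
#' @param max_iter,tol Update-loop controls; a warning is emitted when the
#'   relative loss change is still above `tol` at `max_iter`.
#' @return An `nmf_model` with `W`, `H`, `k`, `seed`, `n_restarts`,
#'   `reconstruction_error` (Frobenius norm of V - WH) and convergence info.
#' @export
factorize <- function(annotation, k, seed = 1L, n_restarts = 5L,
                      max_iter = 1000L, tol = 1e-5) {
  V <- if (inherits(annotation, "phenotype_annotation")) annotation$matrix else annotation
  V <- as.matrix(V)
  if (any(V < 0)) stop("annotation matrix must be non-negative", call. = FALSE)
  if (nrow(V) == 0L || ncol(V) == 0L) stop("annotation matrix is empty", call. = FALSE)
  if (k < 1L || k > min(dim(V))) {
    stop(sprintf("k = %d exceeds the matrix rank bound min(%d, %d)",
                 k, nrow(V), ncol(V)), call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    init <- if (r == 1L) nndsvd_init(V, k) else random_init(V, k)
    fit <- nmf_multiplicative(V, init$W, init$H, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  if (!best$converged) {
    warning(sprintf("NMF did not converge in %d iterations (final error %.6g)",
                    max_iter, best$error), call. = FALSE)
  }
  dimnames(best$W) <- list(rownames(V), paste0("C", seq_len(k)))
  dimnames(best$H) <- list(paste0("C", seq_len(k)), colnames(V))
  structure(
    list(W = best$W, H = best$H, k = as.integer(k), seed = as.integer(seed),
         n_restarts = as.integer(n_restarts),
         reconstruction_error = best$error,
         converged = best$converged, iterations = best$iterations),
    class = "nmf_model"
  )
}

# NNDSVDa: SVD-based non-negative init, zeros replaced by the matrix mean so
# multiplicative updates are not trapped at exact zeros.
nndsvd_init <- function(V, k) {
  s <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k)
  H <- matrix(0, k, ncol(V))
  W[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
  H[1L, ] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
  if (k > 1L) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      n_up <- sqrt(sum(up^2)); n_un <- sqrt(sum(un^2))
      n_vp <- sqrt(sum(vp^2)); n_vn <- sqrt(sum(vn^2))
      if (n_up * n_vp >= n_un * n_vn) {
        sig <- n_up * n_vp
        if (sig > 0) {
          W[, j] <- sqrt(s$d[j] * sig) * up / n_up
          H[j, ] <- sqrt(s$d[j] * sig) * vp / n_vp
        }
      } else {
        sig <- n_un * n_vn
        if (sig > 0) {
          W[, j] <- sqrt(s$d[j] * sig) * un / n_un
          H[j, ] <- sqrt(s$d[j] * sig) * vn / n_vn
        }
      }
    }
  }
  mn <- mean(V)
  W[W <= 0] <- mn
  H[H <= 0] <- mn
  list(W = W, H = H)
}

random_init <- function(V, k) {
  mn <- sqrt(mean(V) / k)
  list(W = matrix(stats::runif(nrow(V) * k, 0, 2 * mn), nrow(V), k),
       H = matrix(stats::runif(k * ncol(V), 0, 2 * mn), k, ncol(V)))
}

nmf_multiplicative <- function(V, W, H, max_iter, tol) {
  eps <- .Machine$double.eps
  err_prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    if (it %% 10L == 0L || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_prev) &&
          abs(err_prev - err) <= tol * max(err_prev, eps)) {
        converged <- TRUE
        err_prev <- err
        break
      }
      err_prev <- err
    }
  }
  list(W = W, H = H, error = sqrt(sum((V - W %*% H)^2)),
       converged = converged, iterations = it)
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("<nmf_model> %d genes x %d terms, k = %d (seed %d, %d restarts)\n",
              nrow(x$W), ncol(x$H), x$k, x$seed, x$n_restarts))
  cat(sprintf("  Frobenius reconstruction error: %.4f\n", x$reconstruction_error))
  invisible(x)
}

#' Tidy an NMF model into long loadings
#'
#' @param x An `nmf_model`.
#' @param matrix Which factor to tidy: "W" (gene loadings, default) or "H"
#'   (component-term weights).
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.nmf_model <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    tibble::tibble(
      gene_id = rep(rownames(x$W), times = ncol(x$W)),
      component = rep(colnames(x$W), each = nrow(x$W)),
      loading = as.vector(x$W)
    )
  } else {
    tibble::tibble(
      component = rep(rownames(x$H), times = ncol(x$H)),
      term_id = rep(colnames(x$H), each = nrow(x$H)),
      weight = as.vector(x$H)
    )
  }
}

#' One-row model summary of an NMF fit
#'
#' @param x An `nmf_model`.
#' @param ... Unused.
#' @export
glance.nmf_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, seed = x$seed, n_restarts = x$n_restarts,
    reconstruction_error = x$reconstruction_error,
    converged = x$converged, iterations = x$iterations
  )
}

#' Top ontology terms of one latent phenotype component
#'
#' @param model An `nmf_model`.
#' @param component Component index (1-based) or name.
#' @param top_n Number of terms to return.
#' @return Tibble of `term_id`, `weight`, descending by weight with ties
#'   broken by term id. An all-zero component yields zero rows and the
#'   `degenerate` attribute set to `TRUE`.
#' @export
annotate_component <- function(model, component, top_n = 10L) {
  stopifnot(inherits(model, "nmf_model"))
  if (is.character(component)) component <- match(component, rownames(model$H))
  if (is.na(component) || component < 1L || component > model$k) {
    stop("component index out of range", call. = FALSE)
  }
  h <- model$H[component, ]
  if (all(h == 0)) {
    out <- tibble::tibble(term_id = character(0), weight = numeric(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ord <- order(-h, names(h))
  sel <- ord[seq_len(min(top_n, length(h)))]
  out <- tibble::tibble(term_id = names(h)[sel], weight = unname(h[sel]))
  attr(out, "degenerate") <- FALSE
  out
}

#' Pleiotropy scores from the NMF feature matrix
#'
#' A gene's pleiotropy score is the sum of its row of W, counting the latent
#' phenotype components it influences. Genes strictly above the
#' `upper_pct` empirical percentile of the score distribution form the
#' pleiotropic set; genes strictly below the `lower_pct` percentile form the
#' non-pleiotropic set. Ties at a threshold belong to neither set.
#'
#' @param model An `nmf_model`.
#' @param upper_pct,lower_pct Percentiles in [0, 100], `lower_pct < upper_pct`.
#' @return A tibble (class `pleiotropy_result`) with `gene_id`, `score` and
#'   `set` in {"pleiotropic", "non_pleiotropic", "neither"}; the percentile
#'   cutoff values are attached as attributes `upper_value`/`lower_value`.
#' @export
pleiotropy_scores <- function(model, upper_pct = 95, lower_pct = 5) {
  stopifnot(inherits(model, "nmf_model"))
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    stop("need 0 <= lower_pct < upper_pct <= 100", call. = FALSE)
  }
  score <- rowSums(model$W)
  up <- stats::quantile(score, upper_pct / 100, names = FALSE)
  lo <- stats::quantile(score, lower_pct / 100, names = FALSE)
  set <- rep("neither", length(score))
  set[score > up] <- "pleiotropic"
  set[score < lo] <- "non_pleiotropic"
  if (all(score == score[1L])) {
    warning("degenerate pleiotropy distribution: all scores equal; both sets empty",
            call. = FALSE)
  }
  out <- tibble::tibble(gene_id = rownames(model$W), score = unname(score),
                        set = set)
  class(out) <- c("pleiotropy_result", class(out))
  attr(out, "upper_value") <- up
  attr(out, "lower_value") <- lo
  attr(out, "upper_pct") <- upper_pct
  attr(out, "lower_pct") <- lower_pct
  out
}
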