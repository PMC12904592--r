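make_model <- function(W) {
  structure(list(W = W, H = matrix(0, ncol(W), 2), k = ncol(W), seed = 1L,
                 n_restarts = 1L, reconstruction_error = 0, converged = TRUE,
                 iterations = 1L),
            class = "nmf_model")
}

test_that("cell contributions sum active-gene weights", {
  W <- matrix(c(0.5, 0.2, 0.3, 0.0,
                0.1, 0.1, 0.4, 0.4), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("C1", "C2")))
  act <- Matrix::Matrix(rbind(c(1, 1, 1, 1),
                              c(0, 0, 0, 0),
                              c(1, 0, 1, 0),
                              c(0, 1, 0, 1),
                              c(1, 1, 0, 0)), sparse = TRUE)
  colnames(act) <- paste0("g", 1:4); rownames(act) <- paste0("c", 1:5)
  cb <- cell_contributions(act, make_model(W), 1, normalize = TRUE)
  expect_equal(cb$component_weight[1], 1.0)   # everything expressed
  expect_equal(cb$component_weight[2], 0.0)   # nothing expressed
  expect_equal(cb$expressed_fraction, c(1, 0, 0.5, 0.5, 0.5))
  # per-cell summation oracle (unnormalized)
  cb_raw <- cell_contributions(act, make_model(W), 2, normalize = FALSE)
  am <- as.matrix(act)
  expect_equal(cb_raw$component_weight,
               as.numeric(am %*% W[, 2]))
  # zero-mass component cannot be normalized
  W0 <- W; W0[, 1] <- 0
  expect_error(cell_contributions(act, make_model(W0), 1, normalize = TRUE),
               "zero total W mass")
})

test_that("regression residuals are OLS residuals", {
  x <- seq(0.1, 1, length.out = 10)
  cb <- tibble::tibble(cell_id = as.character(1:10),
                       cell_type = "A",
                       expressed_fraction = x,
                       component_weight = 0.2 + 0.5 * x)
  r <- regression_residuals(cb)
  expect_true(all(abs(r$residual) < 1e-10))

  cb$component_weight[4] <- cb$component_weight[4] + 0.2
  r2 <- regression_residuals(cb)
  expect_lt(abs(sum(r2$residual)), 1e-8)
  expect_equal(which.max(r2$residual), 4L)

  cb$expressed_fraction <- rep(0.5, 10)
  expect_error(regression_residuals(cb), "distinct")
})

test_that("one-sided KS matches the exhaustive jump-point oracle", {
  expect_equal(ks_one_sided(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  sep <- ks_one_sided(c(10, 11, 12), c(1, 2, 3))
  expect_equal(sep$statistic, 1.0)

  ks_oracle <- function(f, r) {
    pts <- sort(unique(c(f, r)))
    max(0, max(vapply(pts, function(t) mean(r <= t) - mean(f <= t), 0.0)))
  }
  withr::with_seed(71, {
    for (rep in 1:25) {
      m <- sample(2:50, 1); n <- sample(2:50, 1)
      f <- rnorm(m, mean = runif(1, -1, 1))
      r <- rnorm(n)
      mine <- ks_one_sided(f, r)
      expect_equal(mine$statistic, ks_oracle(f, r))
      # independent route: base R computes the same D+ statistic
      expect_equal(mine$statistic,
                   unname(suppressWarnings(
                     stats::ks.test(r, f, alternative = "greater")$statistic)))
    }
  })
  expect_true(ks_one_sided(c(1), c(0, 2))$unreliable)
})

test_that("mediator scan recovers the planted pairs and nothing else dominates", {
  run <- study_run(1)
  hits <- mediator_hits(run)
  expect_true(all(hits))
  med <- run$res$mediators
  expect_true(all(med$ks_matrix >= 0 & med$ks_matrix <= 1))
  expect_identical(med$significant, med$p_matrix < med$alpha)

  # cell-order invariance
  ds <- run$ds
  act <- binarize_activity(ds$atlas, 1)
  perm <- withr::with_seed(72, sample(nrow(act)))
  med_perm <- mediator_scan(act[perm, ], run$res$model,
                            ds$atlas$cells$cell_type[perm],
                            min_cells = 50)
  expect_equal(med_perm$ks_matrix, med$ks_matrix)

  expect_error(mediator_scan(act, run$res$model, ds$atlas$cells$cell_type,
                             min_cells = nrow(act)),
               "no cell type")
})

test_that("permuted cell-type labels break all mediator associations", {
  run <- study_run(1)
  ds <- run$ds
  act <- binarize_activity(ds$atlas, 1)
  model <- run$res$model
  ct <- ds$atlas$cells$cell_type
  types <- unique(ct)
  n_sig <- 0L; n_pairs <- 0L
  p_all <- c()
  for (perm_seed in 1:20) {
    ctp <- withr::with_seed(perm_seed, sample(ct))
    for (comp in seq_len(model$k)) {
      res <- regression_residuals(
        cell_contributions(act, model, comp))$residual
      for (ty in types) {
        f <- ctp == ty
        kk <- ks_one_sided(res[f], res[!f])
        p_all <- c(p_all, kk$p_value)
        n_sig <- n_sig + (kk$p_value < 1e-4)
        n_pairs <- n_pairs + 1L
      }
    }
  }
  expect_lte(n_sig / n_pairs, 1e-3)
  # p-values are roughly uniform under the no-signal permutation null
  ks_dist <- max(abs(sort(p_all) - seq_along(p_all) / length(p_all)))
  expect_lt(ks_dist, 0.1)
})

test_that("KS heatmap clustering orders rows deterministically", {
  ks <- rbind(a = c(0.9, 0.9, 0.0, 0.0),
              b = c(0.9, 0.9, 0.0, 0.0),
              c = c(0.0, 0.0, 0.8, 0.8),
              d = c(0.0, 0.1, 0.7, 0.9))
  colnames(ks) <- paste0("C", 1:4)
  res <- structure(list(ks_matrix = ks, p_matrix = ks * 0,
                        significant = matrix(TRUE, 4, 4,
                                             dimnames = dimnames(ks)),
                        alpha = 1e-4, n_tests = 16L,
                        cell_type_counts = NULL, min_cells = 50L,
                        normalize = TRUE),
                   class = "mediator_result")
  cl <- cluster_heatmap(res)
  ord <- cl$row_order
  # identical rows are adjacent and the two blocks separate
  expect_equal(abs(diff(match(c("a", "b"), ord))), 1)
  expect_true(all(match(c("a", "b"), ord) %in% 1:2) ||
                all(match(c("a", "b"), ord) %in% 3:4))
  # permuting input rows gives the same leaf sequence up to reflection
  res2 <- res
  res2$ks_matrix <- ks[c(3, 1, 4, 2), ]
  res2$p_matrix <- res2$ks_matrix * 0
  res2$significant <- matrix(TRUE, 4, 4, dimnames = dimnames(res2$ks_matrix))
  ord2 <- cluster_heatmap(res2)$row_order
  expect_true(identical(ord2, ord) || identical(ord2, rev(ord)))
  # dendrograms are valid Newick
  tr <- ape::read.tree(text = cl$row_newick)
  expect_setequal(tr$tip.label, rownames(ks))
  # single-row matrices yield a trivial order and no dendrogram
  res3 <- res
  res3$ks_matrix <- ks[1, , drop = FALSE]
  res3$significant <- res$significant[1, , drop = FALSE]
  res3$p_matrix <- res$p_matrix[1, , drop = FALSE]
  cl3 <- cluster_heatmap(res3)
  expect_equal(cl3$row_order, "a")
  expect_null(cl3$row_newick)
})
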