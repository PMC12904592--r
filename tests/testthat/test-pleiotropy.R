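test_that("expression breadth is a per-gene cell fraction", {
  act <- Matrix::Matrix(cbind(all = rep(1, 10), none = rep(0, 10),
                              seven = rep(c(1, 0), c(7, 3))), sparse = TRUE)
  b <- expression_breadth(act)
  expect_equal(b$breadth, c(1, 0, 0.7))
})

test_that("breadth null behaves at its boundary cases and is reproducible", {
  breadth <- tibble::tibble(gene_id = sprintf("g%02d", 1:50),
                            breadth = seq(0, 1, length.out = 50))
  # saturated: the observed set is the entire gene list
  bn <- breadth_null(breadth, list(all = breadth$gene_id), B = 200, seed = 3)
  expect_equal(bn$summary$p_upper, 1)
  expect_equal(bn$summary$p_lower, 1)

  # extreme separation: observed mean above every null mean
  sets <- list(top = breadth$gene_id[48:50])
  bn2 <- breadth_null(breadth, sets, B = 200, seed = 3)
  expect_equal(bn2$summary$p_upper, 1 / 201)
  expect_gt(bn2$summary$p_lower, 0.99)

  bn3 <- breadth_null(breadth, sets, B = 200, seed = 3)
  expect_identical(bn2$null_means, bn3$null_means)
  expect_error(breadth_null(breadth, sets, B = 10, seed = 1), "at least 100")
})

test_that("planted pleiotropic genes are broader than chance", {
  run <- study_run(1)
  bn <- run$res$breadth_null
  p_up <- bn$summary$p_upper[bn$summary$set == "pleiotropic"]
  expect_lte(p_up, 0.001)
  p_lo <- bn$summary$p_lower[bn$summary$set == "non_pleiotropic"]
  expect_lte(p_lo, 0.001)
})

test_that("stage usage records onset and range", {
  sp <- rbind(always = rep(0.5, 12),
              last = c(rep(0, 11), 0.2),
              never = rep(0, 12))
  colnames(sp) <- paste0("s", 1:12)
  su <- stage_usage(sp)
  expect_equal(su$onset_stage, c(1L, 12L, NA))
  expect_equal(su$stage_fraction, c(1, 1 / 12, NA))

  withr::with_seed(61, rp <- matrix(rbinom(30 * 12, 1, 0.3) * runif(360), 30))
  rownames(rp) <- sprintf("g%02d", 1:30); colnames(rp) <- paste0("s", 1:12)
  su2 <- stage_usage(rp)
  for (i in 1:30) {
    on <- which(rp[i, ] > 0)
    expect_equal(su2$onset_stage[i],
                 if (length(on)) as.integer(on[1]) else NA_integer_)
  }
})

test_that("coordinate enrichment finds planted coordinates and is calibrated", {
  # planted case: the gene set is active only at one coordinate
  vals <- matrix(0.05, 40, 6,
                 dimnames = list(sprintf("g%02d", 1:40), paste0("A|s", 1:6)))
  vals[1:10, 3] <- 0.95
  dev <- structure(list(values = vals,
                        coordinates = tibble::tibble(
                          coordinate = colnames(vals), cell_type = "A",
                          stage = 1:6, n_cells = 10L),
                        gene_ids = rownames(vals)), class = "dev_matrix")
  ce <- coordinate_enrichment(dev, sprintf("g%02d", 1:10), B = 500, seed = 2,
                              top_n = 1)
  expect_equal(ce$coordinate[ce$rank == 1], "A|s3")
  expect_true(ce$top[ce$coordinate == "A|s3"])

  # saturated set: observed equals the (degenerate) null exactly
  ce_all <- coordinate_enrichment(dev, rownames(vals), B = 200, seed = 2)
  expect_true(all(ce_all$z == 0))

  # z-scores of random gene sets are approximately standard normal; pooled
  # over independent sets so per-set breadth (which shifts every coordinate
  # of one set coherently) averages out
  vals2 <- withr::with_seed(64,
    matrix(runif(400 * 48), 400, 48,
           dimnames = list(sprintf("g%03d", 1:400),
                           paste0(rep(paste0("ct", 1:8), each = 6), "|s", 1:6))))
  dev2 <- structure(list(values = vals2,
                         coordinates = tibble::tibble(
                           coordinate = colnames(vals2),
                           cell_type = rep(paste0("ct", 1:8), each = 6),
                           stage = rep(1:6, 8), n_cells = 20L),
                         gene_ids = rownames(vals2)), class = "dev_matrix")
  zs <- unlist(lapply(1:25, function(i) {
    s <- withr::with_seed(400 + i, sample(rownames(vals2), 50))
    quiet(coordinate_enrichment(dev2, s, B = 300, seed = 500 + i))$z
  }))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.1)
  expect_gt(stats::sd(zs, na.rm = TRUE), 0.8)
  expect_lt(stats::sd(zs, na.rm = TRUE), 1.2)
})

test_that("pleiotropy distributions by class keep their planted ordering", {
  pl <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e"),
                       score = c(2, 5, 5, 1, 3))
  class(pl) <- c("pleiotropy_result", class(pl))
  labels <- tibble::tibble(gene_id = pl$gene_id,
                           rule_class = c("D-P", "D-p", "D-p", "d-P", "d-P"))
  cp <- pleiotropy_by_class(pl, labels)
  expect_equal(cp$summary$median[cp$summary$rule_class == "D-P"], 2)
  expect_null(cp$densities[["D-P"]])  # singleton: summaries only

  # identical classes give identical summaries
  labels2 <- tibble::tibble(gene_id = c("b", "c", "d", "e"),
                            rule_class = c("D-P", "D-p", "D-P", "D-p"))
  pl2 <- tibble::tibble(gene_id = c("b", "c", "d", "e"), score = c(5, 5, 1, 1))
  cp2 <- pleiotropy_by_class(pl2, labels2, classes = c("D-P", "D-p"))
  expect_equal(cp2$summary$median[1], cp2$summary$median[2])

  run <- study_run(1)
  med <- run$res$class_pleiotropy$summary
  expect_gt(med$median[med$rule_class == "D-P"],
            med$median[med$rule_class == "D-p"])
})
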