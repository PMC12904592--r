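test_that("atlas round-trips through the Matrix Market triplet layout", {
  atl <- tiny_atlas()
  dir <- withr::local_tempdir()
  paths <- write_atlas(atl, dir)
  back <- read_atlas(paths["matrix"], paths["cells"], paths["genes"])
  expect_equal(dim(back$counts), c(6L, 3L))
  expect_equal(as.matrix(back$counts), as.matrix(atl$counts),
               ignore_attr = TRUE)
  expect_equal(back$cells$cell_type, atl$cells$cell_type)
  expect_equal(back$cells$embryo_time, atl$cells$embryo_time)
})

test_that("reader fails loudly on malformed inputs", {
  atl <- tiny_atlas()
  dir <- withr::local_tempdir()
  paths <- write_atlas(atl, dir)

  # annotation row count disagrees with the matrix
  cells <- utils::read.delim(paths["cells"])
  utils::write.table(cells[1:4, ], paths["cells"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_atlas(paths["matrix"], paths["cells"], paths["genes"]),
               "dimension mismatch")

  # unparseable embryo time points at the offending row
  cells$embryo_time <- as.character(cells$embryo_time)
  cells$embryo_time[3] <- "late"
  utils::write.table(cells, paths["cells"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_atlas(paths["matrix"], paths["cells"], paths["genes"]),
               "row 3")

  # negative counts violate the atlas invariant
  expect_error(
    new_expression_atlas(matrix(c(1, -2, 0, 3), 2), c("c1", "c2"),
                         c("g1", "g2")),
    "negative")
  expect_error(
    new_expression_atlas(matrix(0, 2, 2), c("c1", "c1"), c("g1", "g2")),
    "not unique")
})

test_that("binarize_activity thresholds counts and is monotone in min_count", {
  atl <- new_expression_atlas(matrix(c(0, 1, 3, 0), 2), c("c1", "c2"),
                              c("g1", "g2"))
  expect_equal(as.matrix(binarize_activity(atl, 1)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  # all-zero input stays all zero
  z <- new_expression_atlas(matrix(0, 2, 2), c("c1", "c2"), c("g1", "g2"))
  expect_true(all(as.matrix(binarize_activity(z, 1)) == 0))
  # below threshold
  one <- new_expression_atlas(matrix(2, 1, 1), "c1", "g1")
  expect_equal(as.numeric(binarize_activity(one, 3)), 0)
  expect_error(binarize_activity(atl, 0), "positive")

  # raising the threshold can never turn an entry on
  atl2 <- tiny_atlas()
  prev <- as.matrix(binarize_activity(atl2, 1))
  for (mc in 2:4) {
    cur <- as.matrix(binarize_activity(atl2, mc))
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("assign_coordinates bins half-open and handles missing/outside data", {
  atl <- new_expression_atlas(
    matrix(1, 5, 1), paste0("c", 1:5), "g1",
    cell_type = c("A", "A", NA, "A", "A"),
    embryo_time = c(150, 100, 120, 10, 350))
  expect_warning(
    cc <- assign_coordinates(atl, stage_edges = c(0, 100, 200, 300)),
    "clamped")
  expect_equal(cc$stage[1], 2L)           # 150 in [100, 200)
  expect_equal(cc$stage[2], 2L)           # boundary 100 goes right
  expect_true(is.na(cc$stage[3]))         # missing cell type
  expect_equal(cc$stage[4], 1L)           # below grid -> first bin
  expect_equal(cc$stage[5], 3L)           # above grid -> last bin
  expect_error(assign_coordinates(atl, stage_edges = c(1, 1, 2)),
               "strictly increasing")
})

test_that("developmental matrix equals a naive per-coordinate tally", {
  # hand-countable toy: 2 coordinates x 2 genes
  atl <- new_expression_atlas(
    matrix(c(1, 1, 0, 1, 0, 0, 1, 0), nrow = 4),
    paste0("c", 1:4), c("g1", "g2"),
    cell_type = c("A", "A", "A", "B"),
    embryo_time = c(5, 5, 5, 5))
  act <- binarize_activity(atl, 1)
  cc <- assign_coordinates(atl, stage_edges = c(0, 10))
  dev <- quiet(build_developmental_matrix(act, cc, drop_inactive = FALSE))
  expect_equal(unname(dev$values["g1", ]), c(2 / 3, 1))
  expect_equal(unname(dev$values["g2", ]), c(1 / 3, 0))

  # random instance vs a double loop over cells
  withr::with_seed(11, {
    n_cells <- 200; n_genes <- 50
    counts <- matrix(rpois(n_cells * n_genes, 0.7), n_cells)
    types <- sample(LETTERS[1:5], n_cells, replace = TRUE)
    times <- runif(n_cells, 0, 100)
  })
  atl <- new_expression_atlas(counts, sprintf("c%03d", 1:n_cells),
                              sprintf("g%02d", 1:n_genes),
                              cell_type = types, embryo_time = times)
  act <- binarize_activity(atl, 1)
  cc <- assign_coordinates(atl, stage_edges = seq(0, 100, by = 25))
  dev <- quiet(build_developmental_matrix(act, cc, drop_inactive = FALSE))
  acm <- as.matrix(act)
  for (j in seq_len(ncol(dev$values))) {
    ct <- dev$coordinates$cell_type[j]
    st <- dev$coordinates$stage[j]
    at_coord <- which(types == ct & cc$stage == st)
    expect_equal(unname(dev$values[, j]),
                 colSums(acm[at_coord, , drop = FALSE]) / length(at_coord),
                 ignore_attr = TRUE)
  }

  # permuting cell order leaves the matrix unchanged
  perm <- withr::with_seed(2, sample(n_cells))
  atl_p <- new_expression_atlas(counts[perm, ], sprintf("c%03d", 1:n_cells),
                                sprintf("g%02d", 1:n_genes),
                                cell_type = types[perm],
                                embryo_time = times[perm])
  dev_p <- quiet(build_developmental_matrix(
    binarize_activity(atl_p, 1),
    assign_coordinates(atl_p, stage_edges = seq(0, 100, by = 25)),
    drop_inactive = FALSE))
  expect_equal(dev_p$values, dev$values)

  # a gene active everywhere has an all-ones row
  counts2 <- cbind(counts, always = 1)
  atl2 <- new_expression_atlas(counts2, sprintf("c%03d", 1:n_cells),
                               c(sprintf("g%02d", 1:n_genes), "always"),
                               cell_type = types, embryo_time = times)
  dev2 <- quiet(build_developmental_matrix(
    binarize_activity(atl2, 1),
    assign_coordinates(atl2, stage_edges = seq(0, 100, by = 25))))
  expect_true(all(dev2$values["always", ] == 1))

  expect_error(
    build_developmental_matrix(act, cc, min_cells = n_cells + 1L),
    "no developmental coordinate")
})

test_that("stage_profile matches a per-stage hand tally", {
  values <- rbind(
    g1 = c(0.5, 0.0, 0.2, 0.0, 0.9, 0.0),
    g2 = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    g3 = c(1.0, 1.0, 1.0, 1.0, 1.0, 1.0)
  )
  coords <- tibble::tibble(
    coordinate = colnames(values) <- paste0(rep(c("A", "B"), 3), "|s",
                                            rep(1:3, each = 2)),
    cell_type = rep(c("A", "B"), 3), stage = rep(1:3, each = 2),
    n_cells = rep(4L, 6))
  dev <- structure(list(values = values, coordinates = coords,
                        gene_ids = rownames(values)), class = "dev_matrix")
  sp <- stage_profile(dev)
  expect_equal(unname(sp["g1", ]), c(1 / 2, 1 / 2, 1 / 2))
  expect_equal(unname(sp["g2", ]), c(0, 0, 0))
  expect_equal(unname(sp["g3", ]), c(1, 1, 1))
  # thresholded variant ignores weak coordinates
  expect_equal(unname(stage_profile(dev, min_value = 0.4)["g1", ]),
               c(1 / 2, 0, 1 / 2))
})
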