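test_that("generated ontology has disjoint module subtrees under a shared spine", {
  onto <- generate_ontology(n_modules = 2, terms_per_module = 3,
                            shared_root_depth = 2)
  expect_s3_class(onto$ontology, "ontology")   # acyclicity checked on build
  expect_length(onto$module_map, 2L)
  expect_length(unlist(onto$module_map), 6L)
  expect_equal(anyDuplicated(unlist(onto$module_map)), 0L)
  # leaves of different modules share only spine ancestors
  anc <- ontology_ancestors(onto$ontology)
  shared <- intersect(anc[[onto$module_map[[1]][1]]],
                      anc[[onto$module_map[[2]][1]]])
  expect_length(shared, 3L)  # root + 2 spine nodes
  # module map partitions the leaves
  expect_setequal(unlist(onto$module_map), onto$leaves)
})

test_that("noiseless atlases realize the planted activity patterns exactly", {
  cfg <- dp_generator_config(n_genes = 100, activity_noise = 0, seed = 9)
  out <- generate_atlas(cfg)
  act <- binarize_activity(out$atlas, 1)
  coords <- assign_coordinates(out$atlas, stage_edges = out$stage_edges)
  dev <- quiet(build_developmental_matrix(act, coords, drop_inactive = FALSE))
  hk <- out$truth$gene_id[out$truth$true_class %in% c("D-P", "D-p")]
  expect_true(all(dev$values[hk, ] == 1))
  dp_genes <- out$truth$gene_id[out$truth$true_class == "d-P"]
  for (g in dp_genes) {
    expect_equal(sum(dev$values[g, ] > 0), 2L)
  }
})

test_that("generation is deterministic given the seed", {
  d1 <- generate_dp_dataset(dp_generator_config(n_genes = 120, seed = 5))
  d2 <- generate_dp_dataset(dp_generator_config(n_genes = 120, seed = 5))
  expect_identical(as.matrix(d1$atlas$counts), as.matrix(d2$atlas$counts))
  expect_identical(d1$associations, d2$associations)
  expect_identical(d1$truth, d2$truth)
})

test_that("noiseless annotations respect the class contracts", {
  cfg <- dp_generator_config(n_genes = 150, annotation_noise = 0, seed = 6)
  out <- generate_atlas(cfg)
  onto <- generate_ontology(cfg$n_phenotype_modules, cfg$terms_per_module,
                            cfg$shared_root_depth)
  assoc <- generate_annotations(out$truth, onto, annotation_noise = 0, seed = 7)
  leaf_module <- rep(names(onto$module_map), lengths(onto$module_map))
  names(leaf_module) <- unlist(onto$module_map)
  by_gene <- split(assoc$term_id, assoc$gene_id)
  # phenotype-specific genes annotate a single module subtree
  for (g in out$truth$gene_id[out$truth$true_class == "D-p"]) {
    expect_length(unique(leaf_module[by_gene[[g]]]), 1L)
  }
  # systemic genes span at least 3 module subtrees
  for (g in out$truth$gene_id[out$truth$true_class %in% c("D-P", "d-P")]) {
    expect_gte(length(unique(leaf_module[by_gene[[g]]])), 3L)
  }
})

test_that("closure plus module mass accounting recovers true memberships", {
  ds <- generate_dp_dataset(dp_generator_config(seed = 8))
  closed <- ancestor_closure(ds$ontology,
                             associations_to_matrix(ds$associations,
                                                    ds$ontology))
  # majority-module oracle: a gene belongs to the modules whose leaf mass
  # reaches at least half of its best module's leaf mass
  leaf_sets <- ds$module_map
  hits <- vapply(seq_len(nrow(ds$truth)), function(i) {
    g <- ds$truth$gene_id[i]
    mass <- vapply(leaf_sets, function(l) sum(closed$matrix[g, l]), 0.0)
    called <- which(mass >= max(mass) / 2 & mass > 0)
    setequal(called, ds$truth$modules[[i]])
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("generator outputs parse through the standard readers cleanly", {
  cfg <- dp_generator_config(n_genes = 80, activity_noise = 0,
                             annotation_noise = 0, seed = 10)
  ds <- generate_dp_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_atlas(ds$atlas, dir)
  obo <- file.path(dir, "ontology.obo")
  write_obo(ds$ontology, obo)
  assoc_path <- file.path(dir, "associations.tsv")
  write_associations(ds$associations, assoc_path)

  expect_no_warning({
    atl <- read_atlas(paths["matrix"], paths["cells"], paths["genes"])
    ont <- read_ontology(obo)
    assoc <- read_gene_associations(assoc_path)
    associations_to_matrix(assoc, ont)
  })
  expect_equal(as.matrix(atl$counts), as.matrix(ds$atlas$counts),
               ignore_attr = TRUE)
  expect_setequal(ont$term_ids, ds$ontology$term_ids)
})

test_that("drowning the planted signals in noise collapses recovery to chance", {
  cfg <- dp_generator_config(seed = 1, activity_noise = 0.5,
                             annotation_noise = 0.5)
  ds <- generate_dp_dataset(cfg)
  res <- quiet(dp_run(ds$atlas, ds$associations, ds$ontology,
                      study_params(ds$stage_edges)))
  pr <- dplyr::left_join(res$profiles, ds$truth[, c("gene_id", "true_class")],
                         by = "gene_id")
  rec <- vapply(c("D-P", "D-p", "d-P"), function(cl) {
    mean(pr$rule_class[pr$true_class == cl] == cl, na.rm = TRUE)
  }, 0.0)
  expect_lt(mean(rec, na.rm = TRUE), 0.5)
  sp <- cor(pr$median_simD, pr$median_simP, method = "spearman",
            use = "complete.obs")
  expect_lt(abs(sp), 0.3)
})
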