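#' Analysis parameters for the full development-to-phenotype pipeline
#'
#' Collects every tunable the pipeline stages expose, validated up front so
#' a bad setting fails before any compute starts. Defaults mirror the
#' published analysis scale (window 100, k 100, B 10000, resample n 415,
#' mediator min_cells 50, alpha 1e-4, top 100 coordinates); synthetic runs
#' typically override `k`, `B` and the stage binning.
#'
#' @param min_count UMI threshold for activity.
#' @param stage_edges,n_bins Stage binning (see [assign_coordinates()]).
#' @param min_cells Minimum cells per developmental coordinate.
#' @param stage_min_value Activity-fraction floor for the stage profile
#'   (see [stage_profile()]).
#' @param k,nmf_seed,n_restarts NMF settings.
#' @param min_genes_per_term Annotation filter before NMF.
#' @param window Sliding-window size for the trend.
#' @param contingency_edges Percentile boundaries for the contingency.
#' @param span,loess_family Loess settings.
#' @param simD_hi_pct,simD_lo_pct,resid_pct Rule-class cutoffs.
#' @param upper_pct,lower_pct Pleiotropy-set percentiles.
#' @param B Resamples for breadth / coordinate nulls.
#' @param resample_n Resample size for the breadth null (NULL = each set's
#'   own size).
#' @param top_n Top enriched coordinates to flag.
#' @param med_min_cells,alpha,normalize Mediator-scan settings.
#' @param tail Enrichment tail.
#' @param null_seed Seed for the resampling nulls.
#' @return A validated list of class `dp_params`.
#' @export
dp_params <- function(min_count = 1L, stage_edges = NULL, n_bins = 12L,
                      min_cells = 1L, stage_min_value = 0,
                      k = 100L, nmf_seed = 1L, n_restarts = 5L,
                      min_genes_per_term = 2L, window = 100L,
                      contingency_edges = c(20, 40, 60, 80),
                      span = 0.3, loess_family = "symmetric",
                      simD_hi_pct = 70, simD_lo_pct = 30, resid_pct = 20,
                      upper_pct = 95, lower_pct = 5,
                      B = 10000L, resample_n = NULL, top_n = 100L,
                      med_min_cells = 50L, alpha = 1e-4, normalize = TRUE,
                      tail = "greater", null_seed = 1L) {
  stopifnot(min_count >= 1, n_bins >= 1, min_cells >= 0, k >= 1,
            n_restarts >= 1, window >= 1, span > 0, span <= 1,
            simD_lo_pct < simD_hi_pct, resid_pct > 0, resid_pct < 50,
            lower_pct < upper_pct, B >= 100, top_n >= 1,
            med_min_cells >= 1, alpha > 0, alpha < 1)
  out <- as.list(environment())
  class(out) <- "dp_params"
  out
}

#' Run the development-to-phenotype analysis end to end
#'
#' Builds both spaces from an atlas plus ontology annotations, tests the
#' rule, classifies rule-breaking genes, scores pleiotropy and its
#' developmental localization, and scans for mediator cell types. When
#' `out_dir` is given, every stage's table is written as TSV along with a
#' run-metadata JSON (parameter echo, seeds, filter counts), and repeated
#' runs with identical inputs produce byte-identical files.
#'
#' @param atlas An `expression_atlas`.
#' @param associations Gene-term association tibble.
#' @param ontology An `ontology`.
#' @param params A [dp_params()] list.
#' @param out_dir Optional output directory.
#' @return A list with every stage result (`dev`, `annotation`, `model`,
#'   `profiles`, `trend`, `contingency`, `pleiotropy`, `breadth`,
#'   `breadth_null`, `stage_usage`, `coord_enrichment`, `class_pleiotropy`,
#'   `barcodes`, `mediators`, `heatmap`, `enrichment`, `metadata`).
#' @export
dp_run <- function(atlas, associations, ontology, params = dp_params(),
                   out_dir = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"), inherits(ontology, "ontology"),
            inherits(params, "dp_params"))

  # developmental space
  active <- binarize_activity(atlas, params$min_count)
  coords <- assign_coordinates(atlas, params$stage_edges, params$n_bins)
  dev <- build_developmental_matrix(active, coords, params$min_cells)
  stage_prof <- stage_profile(dev, params$stage_min_value)

  # phenotypic space
  direct <- associations_to_matrix(associations, ontology)
  annotation <- filter_annotation(ancestor_closure(ontology, direct),
                                  params$min_genes_per_term)
  shared <- intersect(rownames(dev$values), annotation$gene_ids)
  annotation$matrix <- annotation$matrix[shared, , drop = FALSE]
  annotation$gene_ids <- shared
  annotation <- filter_annotation(annotation, params$min_genes_per_term)
  k <- min(params$k, length(annotation$gene_ids), length(annotation$term_ids))
  model <- factorize(annotation, k = k, seed = params$nmf_seed,
                     n_restarts = params$n_restarts)

  # the rule
  profiles <- similarity_profiles(dev, model)
  trend <- sliding_window_trend(profiles,
                                min(params$window, nrow(profiles)))
  contingency <- quintile_contingency(profiles, params$contingency_edges)
  profiles <- loess_fit_residuals(profiles, span = params$span,
                                  family = params$loess_family)
  profiles <- classify_rule(profiles, params$simD_hi_pct, params$simD_lo_pct,
                            params$resid_pct)
  barcodes <- class_barcodes(stage_prof, model, profiles)

  # pleiotropy
  pleio <- pleiotropy_scores(model, params$upper_pct, params$lower_pct)
  breadth <- expression_breadth(active)
  sets <- list(
    pleiotropic = pleio$gene_id[pleio$set == "pleiotropic"],
    non_pleiotropic = pleio$gene_id[pleio$set == "non_pleiotropic"]
  )
  bnull <- breadth_null(breadth, sets, set_size = params$resample_n,
                        B = params$B, seed = params$null_seed)
  usage <- stage_usage(stage_prof)
  coord_enr <- coordinate_enrichment(dev, sets$pleiotropic, B = params$B,
                                     seed = params$null_seed,
                                     top_n = params$top_n)
  class_pleio <- pleiotropy_by_class(pleio, profiles)

  # mediators
  med <- mediator_scan(active, model, atlas$cells$cell_type,
                       min_cells = params$med_min_cells, alpha = params$alpha,
                       normalize = params$normalize)
  heat <- cluster_heatmap(med)

  # enrichment of the rule-breaking classes against the shared universe
  enr <- list()
  for (cl in c("D-P", "D-p", "d-P")) {
    gs <- intersect(profiles$gene_id[!is.na(profiles$rule_class) &
                                       profiles$rule_class == cl],
                    annotation$gene_ids)
    if (length(gs) > 0L) {
      e <- fisher_enrichment(gs, annotation, tail = params$tail)
      e$gene_class <- cl
      enr[[cl]] <- fdr_adjust(e)
    }
  }
  enrichment <- dplyr::bind_rows(enr)

  metadata <- list(
    params = params[setdiff(names(params), "")],
    n_cells = nrow(atlas$counts), n_genes_atlas = ncol(atlas$counts),
    n_genes_dev = nrow(dev$values), n_coordinates = ncol(dev$values),
    n_genes_shared = length(annotation$gene_ids),
    n_terms = length(annotation$term_ids), k_used = k,
    nmf_error = model$reconstruction_error,
    rule_cutoffs = as.list(attr(profiles, "rule_cutoffs")),
    class_counts = as.list(table(profiles$rule_class)),
    n_mediator_tests = med$n_tests,
    package_version = as.character(utils::packageVersion("dprule"))
  )

  out <- list(dev = dev, stage_profile = stage_prof, annotation = annotation,
              model = model, profiles = profiles, trend = trend,
              contingency = contingency, barcodes = barcodes,
              pleiotropy = pleio, breadth = breadth, breadth_null = bnull,
              stage_usage = usage, coord_enrichment = coord_enr,
              class_pleiotropy = class_pleio, mediators = med,
              heatmap = heat, enrichment = enrichment, metadata = metadata)
  if (!is.null(out_dir)) dp_write_outputs(out, out_dir)
  out
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) if (is.list(df[[nm]])) {
    df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ","), "")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all pipeline artifacts to a directory
#'
#' @param results List from [dp_run()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
dp_write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  dev_df <- data.frame(gene_id = rownames(results$dev$values),
                       results$dev$values, check.names = FALSE)
  write_tsv_plain(dev_df, p("developmental_matrix.tsv"))
  write_tsv_plain(results$dev$coordinates, p("coordinates.tsv"))
  write_tsv_plain(data.frame(gene_id = rownames(results$model$W),
                             results$model$W, check.names = FALSE),
                  p("nmf_W.tsv"))
  write_tsv_plain(data.frame(component = rownames(results$model$H),
                             results$model$H, check.names = FALSE),
                  p("nmf_H.tsv"))
  write_tsv_plain(results$profiles, p("similarity_profiles.tsv"))
  write_tsv_plain(results$trend, p("trend.tsv"))
  write_tsv_plain(tidy(results$contingency), p("contingency.tsv"))
  write_tsv_plain(results$barcodes, p("class_barcodes.tsv"))
  write_tsv_plain(results$pleiotropy, p("pleiotropy.tsv"))
  write_tsv_plain(results$breadth, p("breadth.tsv"))
  write_tsv_plain(results$breadth_null$summary, p("breadth_null.tsv"))
  write_tsv_plain(results$stage_usage, p("stage_usage.tsv"))
  write_tsv_plain(results$coord_enrichment, p("coordinate_enrichment.tsv"))
  write_tsv_plain(tidy(results$mediators), p("mediators.tsv"))
  if (!is.null(results$heatmap$row_newick)) {
    writeLines(results$heatmap$row_newick, p("mediator_rows.nwk"))
  }
  if (!is.null(results$heatmap$col_newick)) {
    writeLines(results$heatmap$col_newick, p("mediator_cols.nwk"))
  }
  if (nrow(results$enrichment) > 0L) {
    write_tsv_plain(results$enrichment, p("enrichment.tsv"))
  }
  jsonlite::write_json(results$metadata, p("run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
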