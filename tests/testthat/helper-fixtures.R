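# Shared fixtures and a memoized full synthetic study run.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# A tiny hand-built atlas: 6 cells (2 types x 2 stages-ish), 3 genes.
tiny_atlas <- function() {
  counts <- Matrix::Matrix(matrix(c(
    # g1 g2 g3
    2, 0, 1,
    1, 0, 0,
    0, 3, 1,
    0, 1, 0,
    4, 0, 2,
    0, 0, 1
  ), nrow = 6, byrow = TRUE), sparse = TRUE)
  new_expression_atlas(
    counts,
    cell_id = paste0("c", 1:6),
    gene_id = paste0("g", 1:3),
    cell_type = c("A", "A", "B", "B", "A", "B"),
    embryo_time = c(105, 160, 110, 215, 230, 150)
  )
}

# chain ontology  L -> M -> R  (leaf to root)
chain_ontology <- function() {
  new_ontology(c("R", "M", "L"),
               list(R = character(0), M = "R", L = "M"))
}

# random DAG ontology for reachability oracles
random_dag_ontology <- function(n_terms = 20L, seed = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("T%02d", seq_len(n_terms))
    parents <- list()
    parents[[ids[1L]]] <- character(0)
    for (i in 2:n_terms) {
      k <- sample(1:min(2, i - 1), 1)
      parents[[ids[i]]] <- sample(ids[seq_len(i - 1L)], k)
    }
    new_ontology(ids, parents)
  })
}

# study conditions for the synthetic analysis (documented in the vignette):
# generator defaults; analysis matched to the generator's known geometry
# (k = number of modules, stage bins = planted stages, activity floor 0.25
# for stage usage), resampling nulls at B = 1000.
study_params <- function(stage_edges) {
  dp_params(k = 6, B = 1000, n_bins = 6, stage_min_value = 0.25,
            stage_edges = stage_edges, window = 100)
}

.study_cache <- new.env(parent = emptyenv())

study_run <- function(seed) {
  key <- paste0("s", seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  ds <- generate_dp_dataset(dp_generator_config(seed = seed))
  res <- quiet(dp_run(ds$atlas, ds$associations, ds$ontology,
                      study_params(ds$stage_edges)))
  out <- list(ds = ds, res = res)
  .study_cache[[key]] <- out
  out
}

# per-class recall of the planted rule classes for one study run
class_recalls <- function(run) {
  pr <- dplyr::left_join(run$res$profiles,
                         run$ds$truth[, c("gene_id", "true_class")],
                         by = "gene_id")
  vapply(c("D-P", "D-p", "d-P"), function(cl) {
    mean(pr$rule_class[pr$true_class == cl] == cl, na.rm = TRUE)
  }, 0.0)
}

# planted mediator pairs recovered as top-KS hits with p < alpha
mediator_hits <- function(run, alpha = 1e-4) {
  mc <- match_components(run$res$model, run$ds$module_map)
  med <- run$res$mediators
  vapply(run$ds$config$mediator_pairs, function(pr) {
    comp <- mc$component[mc$module == paste0("M", pr$module)]
    if (length(comp) != 1L) return(FALSE)
    names(which.max(med$ks_matrix[, comp])) == pr$cell_type &&
      med$p_matrix[pr$cell_type, comp] < alpha
  }, TRUE)
}
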