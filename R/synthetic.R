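#' Configuration for the synthetic development-to-phenotype generator
#'
#' The generator plants four gene classes on a cell-type x stage grid:
#' \describe{
#'   \item{D-P}{housekeeping expression (active at every coordinate) and
#'     systemic phenotypes (annotated to every module) -- rule followers.}
#'   \item{D-p}{housekeeping expression but a single phenotype module --
#'     developmental divergence.}
#'   \item{d-P}{expression restricted to `dp_coords` coordinates but
#'     annotations spanning all modules but one -- phenotypic degeneracy.}
#'   \item{other}{a background continuum: expression breadth graded from
#'     `coord_range[1]` to `coord_range[2]` coordinates, with the number of
#'     annotated modules rising alongside breadth, so that phenotypic module
#'     sharing increases with developmental overlap and the two spaces carry
#'     a recoverable monotone trend.}
#' }
#' Planted mediator pairs make the cells of one type activate the genes
#' annotated exclusively to one module, linking that cell type to the
#' module's latent component.
#'
#' @param n_genes Total genes.
#' @param n_cell_types,n_stages Grid dimensions.
#' @param cells_per_coordinate Mean of the per-coordinate Poisson cell count.
#' @param class_proportions Named proportions over D-P / D-p / d-P / other
#'   (must sum to 1).
#' @param n_phenotype_modules,terms_per_module,shared_root_depth Ontology
#'   layout.
#' @param leaves_per_module Leaf annotations drawn per annotated module.
#' @param annotation_noise,activity_noise Flip rates in [0, 1].
#' @param coord_range Breadth range (number of active coordinates) for
#'   background genes.
#' @param breadth_skew Exponent shaping the background breadth grid
#'   (`k = kmin + u^breadth_skew * (kmax - kmin)`); values above 1 make
#'   narrow genes denser, so the low-similarity end of the trend is well
#'   anchored.
#' @param dp_coords Active-coordinate count for planted d-P genes.
#' @param mediator_pairs List of `list(cell_type =, module =)` pairs.
#' @param mediator_genes Minimum number of marker genes planted per
#'   mediator pair (single-module background genes are reassigned to the
#'   paired module as needed).
#' @param activity_lambda Mean of the zero-truncated Poisson UMI magnitude.
#' @param seed Integer master seed.
#' @return A `dp_generator_config` list.
#' @export
dp_generator_config <- function(n_genes = 500L,
                                n_cell_types = 8L,
                                n_stages = 6L,
                                cells_per_coordinate = 20L,
                                class_proportions = c("D-P" = 0.25, "D-p" = 0.02,
                                                      "d-P" = 0.07, "other" = 0.66),
                                n_phenotype_modules = 6L,
                                terms_per_module = 8L,
                                shared_root_depth = 2L,
                                leaves_per_module = 3L,
                                annotation_noise = 0.05,
                                activity_noise = 0.05,
                                coord_range = c(2L, 40L),
                                breadth_skew = 2,
                                dp_coords = 2L,
                                mediator_pairs = list(
                                  list(cell_type = "ct3", module = 2L),
                                  list(cell_type = "ct6", module = 5L)
                                ),
                                mediator_genes = 10L,
                                activity_lambda = 3,
                                seed = 1L) {
  stopifnot(abs(sum(class_proportions) - 1) < 1e-8,
            all(names(class_proportions) == c("D-P", "D-p", "d-P", "other")),
            annotation_noise >= 0, annotation_noise <= 1,
            activity_noise >= 0, activity_noise <= 1)
  if (dp_coords > n_cell_types * n_stages ||
      coord_range[2L] > n_cell_types * n_stages) {
    stop("coordinate grid too small for the requested coordinate subsets", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), n_cell_types = as.integer(n_cell_types),
         n_stages = as.integer(n_stages),
         cells_per_coordinate = cells_per_coordinate,
         class_proportions = class_proportions,
         n_phenotype_modules = as.integer(n_phenotype_modules),
         terms_per_module = as.integer(terms_per_module),
         shared_root_depth = as.integer(shared_root_depth),
         leaves_per_module = as.integer(leaves_per_module),
         annotation_noise = annotation_noise, activity_noise = activity_noise,
         coord_range = as.integer(coord_range), breadth_skew = breadth_skew,
         dp_coords = as.integer(dp_coords),
         mediator_pairs = mediator_pairs,
         mediator_genes = as.integer(mediator_genes),
         activity_lambda = activity_lambda,
         seed = as.integer(seed)),
    class = "dp_generator_config"
  )
}

#' Generate a synthetic phenotype ontology with planted modules
#'
#' Builds a rooted DAG: a root, a spine chain of depth
#' `shared_root_depth`, then `n_modules` disjoint module subtrees each
#' carrying `terms_per_module` leaf terms. All leaves of different modules
#' share only the spine ancestors.
#'
#' @param n_modules,terms_per_module,shared_root_depth Layout parameters.
#' @param seed Unused (the construction is deterministic); kept for API
#'   symmetry with the other generators.
#' @return List with `ontology`, `module_map` (module label -> leaf term
#'   ids), `module_roots` and `leaves`.
#' @export
generate_ontology <- function(n_modules, terms_per_module,
                              shared_root_depth = 2L, seed = 1L) {
  stopifnot(n_modules >= 1L, terms_per_module >= 1L, shared_root_depth >= 0L)
  counter <- 0L
  new_id <- function() {
    counter <<- counter + 1L
    sprintf("SYN:%07d", counter)
  }
  root <- new_id()
  ids <- root
  nms <- "organism phenotype"
  parents <- list()
  parents[[root]] <- character(0)
  spine_tail <- root
  if (shared_root_depth > 0L) {
    for (d in seq_len(shared_root_depth)) {
      s <- new_id()
      ids <- c(ids, s); nms <- c(nms, sprintf("spine level %d", d))
      parents[[s]] <- spine_tail
      spine_tail <- s
    }
  }
  module_map <- list()
  module_roots <- character(0)
  for (j in seq_len(n_modules)) {
    mr <- new_id()
    ids <- c(ids, mr); nms <- c(nms, sprintf("module %d phenotype", j))
    parents[[mr]] <- spine_tail
    leaves <- character(terms_per_module)
    for (t in seq_len(terms_per_module)) {
      l <- new_id()
      ids <- c(ids, l); nms <- c(nms, sprintf("module %d trait %d", j, t))
      parents[[l]] <- mr
      leaves[t] <- l
    }
    lab <- paste0("M", j)
    module_map[[lab]] <- leaves
    module_roots[lab] <- mr
  }
  list(ontology = new_ontology(ids, parents, nms),
       module_map = module_map, module_roots = module_roots,
       leaves = unlist(module_map, use.names = FALSE))
}

# zero-truncated Poisson draws (active entries must keep a count >= 1)
rztpois <- function(n, lambda) {
  p0 <- stats::dpois(0, lambda)
  stats::qpois(stats::runif(n, p0, 1), lambda)
}

#' Generate a synthetic expression atlas with planted structure
#'
#' Lays cells on the cell-type x stage grid, assigns each gene a class and
#' module membership per the config, and draws UMI counts as Bernoulli
#' activity (planted pattern with `activity_noise` flips) times a
#' zero-truncated Poisson magnitude. Planted mediator cell types
#' additionally activate the genes annotated exclusively to their paired
#' module.
#'
#' @param config A `dp_generator_config`.
#' @return List with `atlas` (an `expression_atlas`), `truth` (per-gene
#'   tibble: class, modules, planted coordinates) and `stage_edges`.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "dp_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n_types <- config$n_cell_types
  n_stages <- config$n_stages
  n_coord <- n_types * n_stages
  types <- paste0("ct", seq_len(n_types))

  # cells per coordinate ~ Poisson(mean), at least 1
  n_cells_coord <- pmax(1L, stats::rpois(n_coord, config$cells_per_coordinate))
  coord_type <- rep(seq_len(n_types), each = n_stages)
  coord_stage <- rep(seq_len(n_stages), times = n_types)
  cell_coord <- rep(seq_len(n_coord), times = n_cells_coord)
  n_cells <- length(cell_coord)
  cell_type <- types[coord_type[cell_coord]]
  # stage s occupies embryo time [10*s, 10*(s+1))
  embryo_time <- 10 * coord_stage[cell_coord] + stats::runif(n_cells, 0, 10)
  stage_edges <- seq(10, 10 * (n_stages + 1), by = 10)

  # gene classes (deterministic counts from proportions)
  n_genes <- config$n_genes
  n_per <- floor(config$class_proportions * n_genes)
  n_per["other"] <- n_genes - sum(n_per[c("D-P", "D-p", "d-P")])
  true_class <- rep(names(n_per), times = n_per)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))

  n_mod <- config$n_phenotype_modules
  modules <- vector("list", n_genes)
  coords <- vector("list", n_genes)
  bg_rank <- 0L
  n_bg <- n_per[["other"]]
  for (i in seq_len(n_genes)) {
    cl <- true_class[i]
    if (cl == "D-P") {
      modules[[i]] <- seq_len(n_mod)
      coords[[i]] <- seq_len(n_coord)
    } else if (cl == "D-p") {
      modules[[i]] <- sample.int(n_mod, 1L)
      coords[[i]] <- seq_len(n_coord)
    } else if (cl == "d-P") {
      modules[[i]] <- sort(sample.int(n_mod, n_mod - 1L))
      coords[[i]] <- sort(sample.int(n_coord, config$dp_coords))
    } else {
      bg_rank <- bg_rank + 1L
      u <- (bg_rank - 0.5) / n_bg
      k <- round(config$coord_range[1L] +
                   u^config$breadth_skew * diff(as.numeric(config$coord_range)))
      m <- 1L + min(n_mod - 2L, floor(u * (n_mod - 1L)))
      modules[[i]] <- sort(sample.int(n_mod, m))
      coords[[i]] <- sort(sample.int(n_coord, k))
    }
  }

  # mediator planting: the background genes annotated exclusively to the
  # paired module become markers of the paired cell type -- their active
  # coordinates are replaced by that type's coordinates, and (below, in the
  # annotation generator) they carry the module's full leaf set, so the
  # type's cells hold a concentrated share of the module's W mass
  mediator_gene <- rep(FALSE, n_genes)
  mediator_type <- rep(NA_character_, n_genes)
  mediator_modules <- vapply(config$mediator_pairs, function(p) p$module, 1L)
  for (pair in config$mediator_pairs) {
    g_idx <- which(true_class == "other" &
                     lengths(modules) == 1L &
                     vapply(modules, function(m) m[1L], 1L) == pair$module)
    short <- config$mediator_genes - length(g_idx)
    if (short > 0L) {
      # top up from single-module background genes of non-mediator modules
      pool <- which(true_class == "other" & !mediator_gene &
                      lengths(modules) == 1L &
                      !vapply(modules, function(m) m[1L], 1L) %in% mediator_modules)
      extra <- sample(pool, min(short, length(pool)))
      for (i in extra) modules[[i]] <- pair$module
      g_idx <- c(g_idx, extra)
    }
    t_idx <- which(types == pair$cell_type)
    if (length(t_idx) != 1L) {
      stop(sprintf("mediator pair names unknown cell type '%s'", pair$cell_type),
           call. = FALSE)
    }
    for (i in g_idx) coords[[i]] <- which(coord_type == t_idx)
    mediator_gene[g_idx] <- TRUE
    mediator_type[g_idx] <- pair$cell_type
  }

  # activity probabilities: planted pattern with symmetric noise flips
  noise <- config$activity_noise
  p_act <- matrix(noise, n_cells, n_genes)
  for (i in seq_len(n_genes)) {
    on_cells <- cell_coord %in% coords[[i]]
    p_act[on_cells, i] <- 1 - noise
  }

  active <- matrix(stats::runif(n_cells * n_genes) < p_act, n_cells, n_genes)
  counts <- matrix(0L, n_cells, n_genes)
  counts[active] <- rztpois(sum(active), config$activity_lambda)
  counts_sp <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  atlas <- new_expression_atlas(
    counts = counts_sp,
    cell_id = sprintf("c%05d", seq_len(n_cells)),
    gene_id = gene_ids,
    cell_type = cell_type,
    embryo_time = embryo_time
  )
  coord_label <- paste0(types[coord_type], "|s", coord_stage)
  truth <- tibble::tibble(
    gene_id = gene_ids,
    true_class = true_class,
    modules = modules,
    n_modules = lengths(modules),
    n_coords = lengths(coords),
    coords = lapply(coords, function(ix) coord_label[ix]),
    mediator_gene = mediator_gene,
    mediator_type = mediator_type
  )
  list(atlas = atlas, truth = truth, stage_edges = stage_edges,
       config = config)
}

#' Generate direct gene-term associations from planted module membership
#'
#' Each gene draws `leaves_per_module` leaf terms from every module it
#' belongs to. Noise removes each planted pair with probability
#' `annotation_noise` and adds one uniformly random leaf per gene with the
#' same probability; a gene losing every annotation keeps one planted leaf
#' so no gene row is empty.
#'
#' @param truth Per-gene truth tibble from [generate_atlas()].
#' @param ontology_out Output of [generate_ontology()].
#' @param annotation_noise Flip rate in [0, 1].
#' @param seed Integer seed.
#' @param leaves_per_module Leaves drawn per annotated module.
#' @return Tibble of `gene_id`, `term_id` pairs.
#' @export
generate_annotations <- function(truth, ontology_out, annotation_noise = 0.05,
                                 seed = 1L, leaves_per_module = 3L) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  mm <- ontology_out$module_map
  all_leaves <- ontology_out$leaves
  genes <- list()
  terms <- list()
  is_mediator <- if ("mediator_gene" %in% names(truth)) truth$mediator_gene else rep(FALSE, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    planted <- unlist(lapply(truth$modules[[i]], function(j) {
      leaves <- mm[[j]]
      if (is_mediator[i]) return(leaves)  # cell-type markers span the module
      sample(leaves, min(leaves_per_module, length(leaves)))
    }), use.names = FALSE)
    keep <- stats::runif(length(planted)) >= annotation_noise
    ann <- planted[keep]
    if (annotation_noise > 0 && stats::runif(1) < annotation_noise) {
      ann <- union(ann, sample(all_leaves, 1L))
    }
    if (length(ann) == 0L) ann <- planted[1L]
    genes[[i]] <- rep(truth$gene_id[i], length(ann))
    terms[[i]] <- ann
  }
  tibble::tibble(gene_id = unlist(genes), term_id = unlist(terms))
}

#' Generate a complete synthetic dataset
#'
#' Composes [generate_ontology()], [generate_atlas()] and
#' [generate_annotations()] under the config's master seed. Two calls with
#' the same config produce identical output.
#'
#' @param config A `dp_generator_config`.
#' @return List with `atlas`, `truth`, `stage_edges`, `ontology`
#'   (ontology object), `module_map`, `module_roots`, `associations` and
#'   the `config`.
#' @export
generate_dp_dataset <- function(config = dp_generator_config()) {
  onto <- generate_ontology(config$n_phenotype_modules, config$terms_per_module,
                            config$shared_root_depth, seed = config$seed)
  atl <- generate_atlas(config)
  assoc <- generate_annotations(atl$truth, onto,
                                annotation_noise = config$annotation_noise,
                                seed = config$seed + 1L,
                                leaves_per_module = config$leaves_per_module)
  list(atlas = atl$atlas, truth = atl$truth, stage_edges = atl$stage_edges,
       ontology = onto$ontology, module_map = onto$module_map,
       module_roots = onto$module_roots, associations = assoc,
       config = config)
}

#' Match NMF components to planted phenotype modules
#'
#' Computes, for every component, the share of its H mass carried by each
#' module's leaf terms, then greedily assigns components to modules
#' (largest share first, each module used at most once) so the matching is
#' one-to-one whenever `k` equals the module count.
#'
#' @param model An `nmf_model` fitted on the synthetic annotation matrix.
#' @param module_map Module label -> leaf term ids (from the generator).
#' @return Tibble with `component`, `module`, `mass_share`.
#' @export
match_components <- function(model, module_map) {
  stopifnot(inherits(model, "nmf_model"))
  comp <- rownames(model$H)
  share <- matrix(0, length(comp), length(module_map),
                  dimnames = list(comp, names(module_map)))
  for (ci in seq_along(comp)) {
    h <- model$H[ci, ]
    mass <- vapply(module_map, function(leaves) {
      sum(h[intersect(leaves, colnames(model$H))])
    }, 0.0)
    tot <- sum(mass)
    if (tot > 0) share[ci, ] <- mass / tot
  }
  assigned_c <- character(0); assigned_m <- character(0); shares <- numeric(0)
  s <- share
  for (step in seq_len(min(dim(share)))) {
    best <- arrayInd(which.max(s), dim(s))
    assigned_c <- c(assigned_c, rownames(s)[best[1L]])
    assigned_m <- c(assigned_m, colnames(s)[best[2L]])
    shares <- c(shares, s[best[1L], best[2L]])
    s <- s[-best[1L], -best[2L], drop = FALSE]
    if (length(s) == 0L) break
  }
  out <- tibble::tibble(component = assigned_c, module = assigned_m,
                        mass_share = shares)
  out[order(out$component), ]
}

#' Write an atlas in the Matrix Market triplet layout
#'
#' @param atlas An `expression_atlas`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  cells <- file.path(dir, "cells.tsv")
  genes <- file.path(dir, "genes.tsv")
  Matrix::writeMM(atlas$counts, mtx)
  utils::write.table(
    data.frame(cell_id = atlas$cells$cell_id,
               cell_type = atlas$cells$cell_type,
               embryo_time = atlas$cells$embryo_time),
    cells, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = atlas$genes$gene_id),
                     genes, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix = mtx, cells = cells, genes = genes))
}

#' Write an ontology as an OBO 1.2 file
#'
#' @param ontology An `ontology`.
#' @param path Output path.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (id in ontology$term_ids) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", ontology$term_names[[id]]), con)
    for (p in ontology$parents[[id]]) {
      writeLines(paste0("is_a: ", p, " ! ", ontology$term_names[[p]]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write gene-term associations as a two-column TSV
#'
#' @param assoc Tibble with `gene_id`, `term_id`.
#' @param path Output path.
#' @export
write_associations <- function(assoc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene_id\tterm_id", con)
  utils::write.table(assoc[, c("gene_id", "term_id")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
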