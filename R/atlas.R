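#' Read a single-cell expression atlas from Matrix Market triplet files
#'
#' Reads a GEO-style triplet layout: a Matrix Market coordinate file holding
#' UMI counts (rows = cells, columns = genes) plus two sidecar TSVs with
#' per-cell and per-gene annotations. The cell table must carry a cell-type
#' column and an embryo-time column (minutes); cells missing either are kept
#' but flagged unusable for coordinate assignment.
#'
#' @param matrix_path Path to the `.mtx` coordinate file (1-based indices).
#' @param cell_annotation_path Path to a TSV with one row per cell.
#' @param gene_annotation_path Path to a TSV with one row per gene.
#' @param cell_type_col,time_col Names of the cell-type and embryo-time
#'   columns in the cell TSV.
#' @param cell_id_col,gene_id_col Optional identifier columns; when `NULL`
#'   the first column of each annotation table is used.
#'
#' @return An `expression_atlas` object: a list with a sparse `counts`
#'   matrix (cells x genes) and `cells` / `genes` annotation tibbles.
#' @export
read_atlas <- function(matrix_path, cell_annotation_path, gene_annotation_path,
                       cell_type_col = "cell_type", time_col = "embryo_time",
                       cell_id_col = NULL, gene_id_col = NULL) {
  counts <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
  cells <- utils::read.delim(cell_annotation_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
  genes <- utils::read.delim(gene_annotation_path, stringsAsFactors = FALSE,
                             check.names = FALSE)

  if (nrow(counts) != nrow(cells) || ncol(counts) != nrow(genes)) {
    stop(sprintf(paste0(
      "atlas dimension mismatch: matrix '%s' is %d x %d but cell table '%s' ",
      "has %d rows and gene table '%s' has %d rows"),
      matrix_path, nrow(counts), ncol(counts),
      cell_annotation_path, nrow(cells),
      gene_annotation_path, nrow(genes)), call. = FALSE)
  }

  if (is.null(cell_id_col)) cell_id_col <- names(cells)[1L]
  if (is.null(gene_id_col)) gene_id_col <- names(genes)[1L]
  for (col in c(cell_type_col, time_col)) {
    if (!col %in% names(cells)) {
      stop(sprintf("cell annotation table lacks required column '%s'", col),
           call. = FALSE)
    }
  }

  time_raw <- cells[[time_col]]
  time_num <- suppressWarnings(as.numeric(time_raw))
  bad <- which(!is.na(time_raw) & trimws(as.character(time_raw)) != "" &
                 is.na(time_num))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable embryo time '%s' at cell row %d of '%s'",
                 time_raw[bad[1L]], bad[1L], cell_annotation_path),
         call. = FALSE)
  }

  cell_type <- as.character(cells[[cell_type_col]])
  cell_type[!is.na(cell_type) & trimws(cell_type) == ""] <- NA_character_

  new_expression_atlas(
    counts = counts,
    cell_id = as.character(cells[[cell_id_col]]),
    gene_id = as.character(genes[[gene_id_col]]),
    cell_type = cell_type,
    embryo_time = time_num,
    cell_meta = tibble::as_tibble(cells),
    gene_meta = tibble::as_tibble(genes)
  )
}

#' Construct and validate an expression atlas
#'
#' @param counts Sparse or dense non-negative count matrix, cells x genes.
#' @param cell_id,gene_id Unique identifier vectors.
#' @param cell_type Character vector per cell (NA allowed).
#' @param embryo_time Numeric minutes per cell (NA allowed).
#' @param lineage Optional lineage label per cell.
#' @param cell_meta,gene_meta Optional extra annotation tibbles.
#' @return An `expression_atlas` object.
#' @export
new_expression_atlas <- function(counts, cell_id, gene_id, cell_type = NULL,
                                 embryo_time = NULL, lineage = NULL,
                                 cell_meta = NULL, gene_meta = NULL) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  n_cells <- nrow(counts)
  n_genes <- ncol(counts)
  stopifnot(length(cell_id) == n_cells, length(gene_id) == n_genes)
  if (anyDuplicated(cell_id)) stop("cell identifiers are not unique", call. = FALSE)
  if (anyDuplicated(gene_id)) stop("gene identifiers are not unique", call. = FALSE)
  if (length(counts@x) && min(counts@x) < 0) {
    stop("atlas counts contain negative values", call. = FALSE)
  }
  if (is.null(cell_type)) cell_type <- rep(NA_character_, n_cells)
  if (is.null(embryo_time)) embryo_time <- rep(NA_real_, n_cells)
  if (any(embryo_time < 0, na.rm = TRUE)) {
    stop("embryo times must be non-negative", call. = FALSE)
  }
  rownames(counts) <- cell_id
  colnames(counts) <- gene_id
  cells <- tibble::tibble(
    cell_id = as.character(cell_id),
    cell_type = as.character(cell_type),
    embryo_time = as.numeric(embryo_time)
  )
  if (!is.null(lineage)) cells$lineage <- as.character(lineage)
  cells$usable <- !is.na(cells$cell_type) & !is.na(cells$embryo_time)
  structure(
    list(counts = counts, cells = cells,
         genes = tibble::tibble(gene_id = as.character(gene_id)),
         cell_meta = cell_meta, gene_meta = gene_meta),
    class = "expression_atlas"
  )
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("<expression_atlas> %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  annotated cells (type & time): %d\n", sum(x$cells$usable)))
  invisible(x)
}

#' Binarize atlas activity
#'
#' A gene is "active" in a cell when its UMI count reaches `min_count`
#' (default 1, i.e. presence of any UMI).
#'
#' @param atlas An `expression_atlas`.
#' @param min_count Positive integer activity threshold.
#' @return Sparse binary matrix, cells x genes.
#' @export
binarize_activity <- function(atlas, min_count = 1L) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (length(min_count) != 1L || is.na(min_count) || min_count < 1) {
    stop("min_count must be a positive integer", call. = FALSE)
  }
  x <- atlas$counts
  x@x <- as.numeric(x@x >= min_count)
  Matrix::drop0(x)
}

#' Assign each cell to a developmental coordinate
#'
#' A coordinate is a (cell type, embryo-time bin) pair. Binning is half-open
#' `[e_j, e_{j+1})`; times below the first edge or at/above the last edge are
#' clamped to the first/last bin with a warning giving the clamp count. Cells
#' missing a cell type or time get `NA` coordinates and are excluded
#' downstream.
#'
#' @param atlas An `expression_atlas`.
#' @param stage_edges Strictly increasing numeric edge vector. When `NULL` a
#'   uniform grid over the observed time range with `n_bins` bins is used.
#' @param n_bins Number of bins for the default uniform grid.
#' @return Tibble with one row per cell: `cell_id`, `cell_type`, `stage`
#'   (integer bin index), `coordinate` ("type|stage" label or NA). Bin edges
#'   are attached as the `stage_edges` attribute.
#' @export
assign_coordinates <- function(atlas, stage_edges = NULL, n_bins = 12L) {
  stopifnot(inherits(atlas, "expression_atlas"))
  tm <- atlas$cells$embryo_time
  if (is.null(stage_edges)) {
    rng <- range(tm, na.rm = TRUE)
    if (!all(is.finite(rng))) stop("no embryo times available to bin", call. = FALSE)
    # widen the top edge a hair so the latest observed cell falls inside
    stage_edges <- seq(rng[1L], rng[2L] + 1e-9 + diff(rng) * 1e-9,
                       length.out = n_bins + 1L)
  }
  if (any(diff(stage_edges) <= 0)) {
    stop("stage_edges must be strictly increasing", call. = FALSE)
  }
  n_stage <- length(stage_edges) - 1L
  bin <- findInterval(tm, stage_edges)
  clamped <- sum(bin < 1L | bin > n_stage, na.rm = TRUE)
  if (clamped > 0L) {
    warning(sprintf("%d cells had embryo times outside the stage grid; clamped to end bins",
                    clamped), call. = FALSE)
  }
  bin[bin < 1L] <- 1L
  bin[bin > n_stage] <- n_stage
  out <- tibble::tibble(
    cell_id = atlas$cells$cell_id,
    cell_type = atlas$cells$cell_type,
    stage = ifelse(atlas$cells$usable, bin, NA_integer_)
  )
  out$stage <- as.integer(out$stage)
  out$cell_type[is.na(out$stage)] <- NA_character_
  out$coordinate <- ifelse(is.na(out$stage), NA_character_,
                           paste0(out$cell_type, "|s", out$stage))
  attr(out, "stage_edges") <- stage_edges
  attr(out, "n_stages") <- n_stage
  out
}

#' Build the developmental matrix of per-gene activity fractions
#'
#' Entry (gene, coordinate) is the fraction of cells at that (cell type,
#' stage) coordinate in which the gene is active. Coordinates observed in
#' fewer than `min_cells` cells are dropped so every fraction is estimated
#' from observed cells; genes never active in any retained cell are dropped
#' with a message.
#'
#' @param active Binary cells x genes matrix from [binarize_activity()].
#' @param coords Per-cell coordinate tibble from [assign_coordinates()].
#' @param min_cells Minimum cells per retained coordinate.
#' @param drop_inactive Drop genes with all-zero rows (default TRUE).
#' @return A `dev_matrix` object: dense `values` (genes x coordinates, in
#'   [0,1]), a `coordinates` tibble (cell_type, stage, n_cells) and
#'   `gene_ids`. Columns are ordered cell type lexicographic, then stage.
#' @export
build_developmental_matrix <- function(active, coords, min_cells = 1L,
                                       drop_inactive = TRUE) {
  stopifnot(nrow(active) == nrow(coords))
  keep <- !is.na(coords$coordinate)
  act <- active[keep, , drop = FALSE]
  cc <- coords[keep, , drop = FALSE]
  key <- paste0(cc$cell_type, "|s", formatC(cc$stage, width = 3L, flag = "0"))
  keys <- sort(unique(key))
  n_at <- as.integer(table(key)[keys])
  ok <- n_at >= min_cells
  if (!any(ok)) {
    stop(sprintf("no developmental coordinate has >= %d cells", min_cells),
         call. = FALSE)
  }
  keys <- keys[ok]
  n_at <- n_at[ok]
  in_keep <- key %in% keys
  act <- act[in_keep, , drop = FALSE]
  key <- key[in_keep]
  # indicator (cells x coords) so crossprod gives active-cell counts per coord
  fk <- factor(key, levels = keys)
  ind <- Matrix::sparseMatrix(i = seq_along(key), j = as.integer(fk),
                              x = 1, dims = c(length(key), length(keys)))
  counts_mat <- as.matrix(Matrix::crossprod(act, ind))  # genes x coords
  values <- sweep(counts_mat, 2L, n_at, "/")
  rownames(values) <- colnames(active)
  colnames(values) <- keys
  if (drop_inactive) {
    zero <- rowSums(values) == 0
    if (any(zero)) {
      message(sprintf("dropping %d genes never active in retained cells", sum(zero)))
      values <- values[!zero, , drop = FALSE]
    }
  }
  parts <- strsplit(keys, "|s", fixed = TRUE)
  coord_tbl <- tibble::tibble(
    coordinate = keys,
    cell_type = vapply(parts, `[`, "", 1L),
    stage = as.integer(vapply(parts, `[`, "", 2L)),
    n_cells = n_at
  )
  structure(
    list(values = values, coordinates = coord_tbl,
         gene_ids = rownames(values)),
    class = "dev_matrix"
  )
}

#' @export
print.dev_matrix <- function(x, ...) {
  cat(sprintf("<dev_matrix> %d genes x %d coordinates (%d cell types, %d stages)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$coordinates$cell_type)),
              length(unique(x$coordinates$stage))))
  invisible(x)
}

#' Tidy a developmental matrix into long format
#'
#' @param x A `dev_matrix`.
#' @param ... Unused.
#' @return Tibble with columns gene_id, coordinate, cell_type, stage, value.
#' @export
tidy.dev_matrix <- function(x, ...) {
  long <- tibble::tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    coordinate = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  dplyr::left_join(long, x$coordinates, by = "coordinate")
}

#' Fraction of cell types expressing each gene at each stage
#'
#' For gene i and stage s, the fraction of cell types observed at s whose
#' developmental-matrix entry for i exceeds `min_value`. Stages with zero
#' observed cell types yield `NA`. The default `min_value = 0` counts any
#' active cell; raising it requires a minimum fraction of active cells per
#' coordinate, which suppresses sporadic background activity in noisy data.
#'
#' @param dev A `dev_matrix`.
#' @param min_value Minimum activity fraction for a cell type to count as
#'   expressing (default 0, i.e. strictly positive).
#' @return Dense genes x stages matrix with entries in [0,1] (or NA).
#' @export
stage_profile <- function(dev, min_value = 0) {
  stopifnot(inherits(dev, "dev_matrix"))
  stages <- sort(unique(dev$coordinates$stage))
  out <- matrix(NA_real_, nrow(dev$values), length(stages),
                dimnames = list(rownames(dev$values), paste0("s", stages)))
  for (k in seq_along(stages)) {
    cols <- which(dev$coordinates$stage == stages[k])
    if (length(cols) == 0L) next
    sub <- dev$values[, cols, drop = FALSE]
    out[, k] <- rowSums(sub > min_value) / length(cols)
  }
  out
}
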