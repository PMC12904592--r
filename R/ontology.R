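#' Parse an OBO ontology file
#'
#' Minimal OBO 1.2 reader: `[Term]` stanzas with `id`, `name`, `is_a` and
#' `is_obsolete` tags. Obsolete terms are excluded; `is_a` links to them are
#' dropped with the term. The parent relation must be acyclic and every
#' referenced parent must be defined.
#'
#' @param obo_path Path to the `.obo` file.
#' @return An `ontology` object: `term_ids`, `term_names`, `parents` (named
#'   list of direct is_a parents) and `roots`.
#' @export
read_ontology <- function(obo_path) {
  lines <- readLines(obo_path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) stop("no [Term] stanzas found", call. = FALSE)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); parents <- list()
  obsolete <- character(0)
  for (s in seq_along(stanza_starts)) {
    chunk <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    chunk <- chunk[!grepl("^\\s*$", chunk)]
    # a stanza ends at the next bracketed header (e.g. [Typedef])
    hdr <- grep("^\\[", chunk)
    if (length(hdr)) chunk <- chunk[seq_len(hdr[1L] - 1L)]
    get_tag <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "", grep(paste0("^", tag, ":"), chunk, value = TRUE))
      sub("\\s*(!.*)?$", "", v)
    }
    id <- get_tag("id")[1L]
    if (is.na(id) || !nzchar(id)) next
    if (any(grepl("^is_obsolete:\\s*true", chunk))) {
      obsolete <- c(obsolete, id)
      next
    }
    isa <- get_tag("is_a")
    isa <- vapply(strsplit(isa, "!", fixed = TRUE), function(z) trimws(z[1L]), "")
    ids <- c(ids, id)
    nm <- get_tag("name")[1L]
    nms <- c(nms, if (is.na(nm)) id else nm)
    parents[[id]] <- isa[nzchar(isa)]
  }
  # drop links to terms that were excluded (e.g. obsolete) but fail on truly
  # unknown parents, which indicate a malformed file
  known <- ids
  for (id in ids) {
    parents[[id]] <- setdiff(parents[[id]], obsolete)
    miss <- setdiff(parents[[id]], known)
    if (length(miss)) {
      stop(sprintf("term '%s' references undefined parent '%s'", id, miss[1L]),
           call. = FALSE)
    }
  }
  new_ontology(term_ids = ids, parents = parents, term_names = nms)
}

#' Construct and validate an ontology
#'
#' @param term_ids Character vector of term identifiers.
#' @param parents Named list mapping each term to its direct is_a parents.
#' @param term_names Optional human-readable names.
#' @return An `ontology` object.
#' @export
new_ontology <- function(term_ids, parents, term_names = NULL) {
  if (anyDuplicated(term_ids)) stop("duplicate term ids", call. = FALSE)
  parents <- parents[term_ids]
  names(parents) <- term_ids
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  cyc <- find_cycle(term_ids, parents)
  if (!is.null(cyc)) {
    stop(sprintf("ontology parent relation contains a cycle: %s",
                 paste(cyc, collapse = " -> ")), call. = FALSE)
  }
  roots <- term_ids[vapply(parents, length, 1L) == 0L]
  if (is.null(term_names)) term_names <- term_ids
  structure(
    list(term_ids = term_ids, term_names = stats::setNames(term_names, term_ids),
         parents = parents, roots = roots),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d roots\n",
              length(x$term_ids), length(x$roots)))
  invisible(x)
}

# Kahn's algorithm; returns one cycle (as a term path) or NULL when acyclic.
find_cycle <- function(term_ids, parents) {
  out_deg <- vapply(parents, function(p) length(p), 1L)
  children <- split(
    rep(names(parents), lengths(parents)),
    unlist(parents, use.names = FALSE)
  )
  queue <- term_ids[out_deg == 0L]
  seen <- 0L
  deg <- out_deg
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[t]]) {
      deg[[ch]] <- deg[[ch]] - 1L
      if (deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(term_ids)) return(NULL)
  # walk parent links inside the residual graph until a repeat closes the loop
  residual <- term_ids[deg > 0L]
  path <- residual[1L]
  repeat {
    nxt <- intersect(parents[[path[length(path)]]], residual)[1L]
    if (nxt %in% path) {
      return(c(path[which(path == nxt)[1L]:length(path)], nxt))
    }
    path <- c(path, nxt)
  }
}

#' All ancestors of each ontology term
#'
#' @param ontology An `ontology`.
#' @param include_self Include the term itself (default FALSE).
#' @return Named list mapping each term to its ancestor term ids.
#' @export
ontology_ancestors <- function(ontology, include_self = FALSE) {
  stopifnot(inherits(ontology, "ontology"))
  anc <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    p <- ontology$parents[[t]]
    res <- unique(c(p, unlist(lapply(p, get_anc), use.names = FALSE)))
    anc[[t]] <- res
    res
  }
  out <- lapply(ontology$term_ids, get_anc)
  names(out) <- ontology$term_ids
  if (include_self) out <- mapply(function(t, a) unique(c(t, a)),
                                  ontology$term_ids, out, SIMPLIFY = FALSE)
  out
}

#' Read a two-column gene-term association table
#'
#' @param path TSV with columns gene_id, term_id (no header); lines starting
#'   with `#` are comments.
#' @return Tibble with columns `gene_id`, `term_id`.
#' @export
read_gene_associations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("gene_id", "term_id"))
  tibble::as_tibble(df)
}

#' Build a direct binary gene x term matrix from association pairs
#'
#' Associations to terms absent from the ontology are skipped with a warning
#' giving the skipped-pair count.
#'
#' @param assoc Tibble/data frame with `gene_id` and `term_id` columns.
#' @param ontology An `ontology`.
#' @return Sparse binary genes x terms matrix over all ontology terms.
#' @export
associations_to_matrix <- function(assoc, ontology) {
  stopifnot(inherits(ontology, "ontology"))
  known <- assoc$term_id %in% ontology$term_ids
  if (!all(known)) {
    warning(sprintf("skipping %d associations to unknown terms", sum(!known)),
            call. = FALSE)
    assoc <- assoc[known, , drop = FALSE]
  }
  genes <- sort(unique(assoc$gene_id))
  gi <- match(assoc$gene_id, genes)
  ti <- match(assoc$term_id, ontology$term_ids)
  m <- Matrix::sparseMatrix(i = gi, j = ti, x = 1,
                            dims = c(length(genes), length(ontology$term_ids)),
                            dimnames = list(genes, ontology$term_ids))
  m@x[] <- 1
  methods::as(m, "CsparseMatrix")
}

#' Ancestor-closed phenotype annotation matrix
#'
#' Extends each gene's direct annotations to every term that subsumes them:
#' `matrix[g, t] = 1` iff t is a direct annotation of g or an ancestor of
#' one. Closure is idempotent.
#'
#' @param ontology An `ontology`.
#' @param direct Binary genes x terms matrix; column names must be a subset
#'   of the ontology's terms (columns for missing terms are added as zeros).
#' @return A `phenotype_annotation` object with the closed sparse binary
#'   `matrix`, `gene_ids` and `term_ids`.
#' @export
ancestor_closure <- function(ontology, direct) {
  stopifnot(inherits(ontology, "ontology"))
  terms <- ontology$term_ids
  if (is.null(colnames(direct))) {
    stopifnot(ncol(direct) == length(terms))
    colnames(direct) <- terms
  }
  unknown <- setdiff(colnames(direct), terms)
  if (length(unknown)) {
    stop(sprintf("direct annotation matrix has columns absent from the ontology (e.g. '%s')",
                 unknown[1L]), call. = FALSE)
  }
  direct <- methods::as(methods::as(direct, "CsparseMatrix"), "generalMatrix")
  full <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(nrow(direct), length(terms)),
                               dimnames = list(rownames(direct), terms))
  full[, colnames(direct)] <- direct
  # term -> (self + ancestors) reachability matrix; closed = direct %*% reach
  anc <- ontology_ancestors(ontology, include_self = TRUE)
  ti <- rep(seq_along(terms), lengths(anc))
  tj <- match(unlist(anc, use.names = FALSE), terms)
  reach <- Matrix::sparseMatrix(i = ti, j = tj, x = 1,
                                dims = c(length(terms), length(terms)),
                                dimnames = list(terms, terms))
  closed <- methods::as(full %*% reach, "CsparseMatrix")
  dimnames(closed) <- list(rownames(direct), terms)
  closed@x <- rep(1, length(closed@x))
  structure(
    list(matrix = Matrix::drop0(closed),
         gene_ids = rownames(direct), term_ids = terms),
    class = "phenotype_annotation"
  )
}

#' @export
print.phenotype_annotation <- function(x, ...) {
  cat(sprintf("<phenotype_annotation> %d genes x %d terms (%d annotations)\n",
              length(x$gene_ids), length(x$term_ids),
              Matrix::nnzero(x$matrix)))
  invisible(x)
}

#' Filter a phenotype annotation before factorization
#'
#' Drops terms annotated to fewer than `min_genes` genes (which would create
#' rank-deficient all-zero or near-constant columns) and then genes left with
#' no surviving annotation.
#'
#' @param annotation A `phenotype_annotation`.
#' @param min_genes Minimum genes per retained term.
#' @return A filtered `phenotype_annotation`.
#' @export
filter_annotation <- function(annotation, min_genes = 2L) {
  stopifnot(inherits(annotation, "phenotype_annotation"))
  m <- annotation$matrix
  keep_t <- Matrix::colSums(m) >= min_genes
  m <- m[, keep_t, drop = FALSE]
  keep_g <- Matrix::rowSums(m) > 0
  if (any(!keep_g)) {
    message(sprintf("dropping %d genes with no surviving annotation", sum(!keep_g)))
  }
  m <- m[keep_g, , drop = FALSE]
  structure(list(matrix = m, gene_ids = rownames(m), term_ids = colnames(m)),
            class = "phenotype_annotation")
}
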