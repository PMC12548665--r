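#' Construct and validate a structural connectivity matrix
#'
#' A structural connectivity (SC) matrix is a square, symmetric, non-negative
#' weighted adjacency matrix with a zero diagonal; entry \eqn{(i,j)} holds the
#' connection strength between brain regions \eqn{i} and \eqn{j} (e.g. a
#' volume-normalized streamline count). `connectivity_matrix()` validates its
#' input, symmetrizes away floating-point asymmetry below the tolerance, and
#' returns a classed matrix.
#'
#' Validation rules:
#' * square, all entries finite and `>= 0`;
#' * symmetric within `tol` (after the check the matrix is replaced by
#'   `(w + t(w)) / 2` so downstream code sees exact symmetry);
#' * diagonal entries with absolute value `<= tol` are forced to zero,
#'   anything larger is an error;
#' * at least 3 nodes.
#'
#' @param weights square numeric matrix of edge weights.
#' @param node_labels optional character vector of region names; defaults to
#'   `"n1" ... "nN"`.
#' @param tol symmetry / diagonal tolerance (default `1e-8`).
#' @return a matrix of class `"connectivity_matrix"` with a `node_labels`
#'   attribute.
#' @examples
#' w <- matrix(0, 4, 4); w[2, 1] <- w[1, 2] <- 3
#' m <- connectivity_matrix(w)
#' n_nodes(m)
#' @export
connectivity_matrix <- function(weights, node_labels = NULL, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("'weights' must be a numeric matrix", call. = FALSE)
  n <- nrow(weights)
  if (ncol(weights) != n)
    stop(sprintf("matrix is not square: %d x %d", n, ncol(weights)),
         call. = FALSE)
  if (n < 3)
    stop("a connectivity matrix needs at least 3 nodes", call. = FALSE)
  bad <- which(!is.finite(weights))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(weights))
    stop(sprintf("non-finite weight at (%d, %d)", ij[1L], ij[2L]),
         call. = FALSE)
  }
  asym <- abs(weights - t(weights))
  if (max(asym) > tol) {
    ij <- arrayInd(which.max(asym), dim(weights))
    stop(sprintf(
      "asymmetric input: |w(%d,%d) - w(%d,%d)| = %.3g exceeds tol %.1g",
      ij[1L], ij[2L], ij[2L], ij[1L], max(asym), tol), call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  dg <- diag(weights)
  if (any(abs(dg) > tol)) {
    i <- which.max(abs(dg))
    stop(sprintf("nonzero diagonal: w(%d,%d) = %.3g", i, i, dg[i]),
         call. = FALSE)
  }
  diag(weights) <- 0
  neg <- which(weights < 0)
  if (length(neg)) {
    ij <- arrayInd(neg[1L], dim(weights))
    stop(sprintf("negative weight %.3g at (%d, %d)",
                 weights[neg[1L]], ij[1L], ij[2L]), call. = FALSE)
  }
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  if (length(node_labels) != n)
    stop("'node_labels' length must equal the number of nodes", call. = FALSE)
  dimnames(weights) <- NULL
  structure(weights, node_labels = as.character(node_labels),
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @rdname connectivity_matrix
#' @param m a `connectivity_matrix`.
#' @export
n_nodes <- function(m) nrow(m)

#' @rdname connectivity_matrix
#' @export
node_labels <- function(m) attr(m, "node_labels")

#' @export
print.connectivity_matrix <- function(x, ...) {
  n <- nrow(x)
  e <- x[lower.tri(x)]
  cat(sprintf("Connectivity matrix: %d nodes, density %.3f, weight range [%.3g, %.3g]\n",
              n, mean(e > 0), min(e), max(e)))
  invisible(x)
}

# strip class/attrs for internal numeric work
as_weight_matrix <- function(m) {
  w <- unclass(as.matrix(m))
  attr(w, "node_labels") <- NULL
  w
}

#' Vectorize the strict lower triangle of a connectivity matrix
#'
#' Flattens a symmetric matrix into its strict lower triangle in row-major
#' order: rows `i = 2..n`, columns `j = 1..i-1` (1-based), i.e. the edge
#' ordering `(2,1), (3,1), (3,2), (4,1), ...`. This is the fixed edge-vector
#' convention used everywhere in the package (decoder outputs, prediction
#' features, weight-reliability tables). `matricize()` is its exact inverse.
#'
#' @param m a `connectivity_matrix` (or plain symmetric matrix).
#' @return numeric vector of length `n(n-1)/2` with attribute `n_nodes`.
#' @seealso [matricize()]
#' @export
vectorize_lower_triangle <- function(m) {
  if (!inherits(m, "connectivity_matrix"))
    m <- connectivity_matrix(as.matrix(m))
  w <- as_weight_matrix(m)
  # t(w)[upper.tri(w)] enumerates the lower triangle in row-major order
  v <- t(w)[upper.tri(w)]
  structure(v, n_nodes = nrow(w))
}

#' Rebuild a symmetric matrix from a lower-triangle edge vector
#'
#' Inverse of [vectorize_lower_triangle()]: places the values back into the
#' strict lower triangle (row-major), mirrors them, and zeroes the diagonal.
#' Negative entries are clipped at zero before validation, matching the
#' non-negativity contract of connectivity matrices (decoder outputs are
#' non-negative by construction, so clipping only absorbs round-off).
#'
#' @param v numeric edge vector whose length is a triangular number
#'   `n(n-1)/2`.
#' @param node_labels optional region names for the rebuilt matrix.
#' @return a `connectivity_matrix`.
#' @export
matricize <- function(v, node_labels = NULL) {
  L <- length(v)
  n <- (1 + sqrt(1 + 8 * L)) / 2
  if (abs(n - round(n)) > 1e-9)
    stop(sprintf("length %d is not a triangular number n(n-1)/2", L),
         call. = FALSE)
  n <- as.integer(round(n))
  w <- matrix(0, n, n)
  tw <- t(w)
  tw[upper.tri(tw)] <- v
  w <- t(tw)
  w <- w + t(w)
  connectivity_matrix(pmax(w, 0), node_labels = node_labels)
}

#' Permute the node order of a connectivity matrix
#'
#' Applies a node permutation, e.g. to align regions with a functional
#' network ordering. `perm` is 1-based: the new node `i` is the old node
#' `perm[i]`, so `w'[i, j] = w[perm[i], perm[j]]`; labels move with their
#' nodes.
#'
#' @param m a `connectivity_matrix`.
#' @param perm integer permutation of `1:n_nodes(m)`.
#' @export
reorder_nodes <- function(m, perm) {
  n <- n_nodes(m)
  perm <- as.integer(perm)
  if (length(perm) != n || anyNA(perm) || !setequal(perm, seq_len(n)))
    stop("'perm' must be a permutation of 1..n_nodes", call. = FALSE)
  connectivity_matrix(as_weight_matrix(m)[perm, perm],
                      node_labels = node_labels(m)[perm])
}

#' Bundle connectivity matrices with cognitive scores
#'
#' A connectome dataset is an ordered collection of `(matrix, score)` pairs
#' sharing one parcellation. Matrices synthesized by augmentation carry
#' `synthetic = TRUE` in the scores table; the prediction benchmark uses that
#' flag to keep synthesized samples out of validation and test folds.
#'
#' @param matrices list of `connectivity_matrix` objects (or plain matrices).
#' @param scores data frame with columns `subject_id`, `score`, and optional
#'   logical `synthetic`; one row per matrix, same order.
#' @param atlas_name label for the parcellation (free text).
#' @return object of class `"connectome_dataset"`.
#' @export
connectome_dataset <- function(matrices, scores, atlas_name = "custom") {
  if (!length(matrices)) stop("empty dataset", call. = FALSE)
  if (!is.data.frame(scores) ||
      !all(c("subject_id", "score") %in% names(scores)))
    stop("'scores' needs columns subject_id and score", call. = FALSE)
  if (nrow(scores) != length(matrices))
    stop("one scores row per matrix required", call. = FALSE)
  if (!is.numeric(scores$score) || any(!is.finite(scores$score)))
    stop("scores must be finite numbers", call. = FALSE)
  scores$subject_id <- as.character(scores$subject_id)
  if (anyDuplicated(scores$subject_id))
    stop("duplicate subject_id: ",
         scores$subject_id[duplicated(scores$subject_id)][1L], call. = FALSE)
  if (is.null(scores$synthetic)) scores$synthetic <- FALSE
  matrices <- lapply(matrices, function(w)
    if (inherits(w, "connectivity_matrix")) w
    else connectivity_matrix(as.matrix(w)))
  ns <- vapply(matrices, n_nodes, 1L)
  if (length(unique(ns)) != 1L)
    stop("all matrices must share the node count; saw ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  labs <- node_labels(matrices[[1L]])
  same <- vapply(matrices, function(m) identical(node_labels(m), labs), TRUE)
  if (!all(same)) stop("all matrices must share node labels", call. = FALSE)
  rownames(scores) <- NULL
  structure(list(matrices = matrices,
                 scores = scores[, c("subject_id", "score", "synthetic")],
                 atlas_name = atlas_name),
            class = "connectome_dataset")
}

#' @export
print.connectome_dataset <- function(x, ...) {
  cat(sprintf("Connectome dataset: %d subjects (%d synthetic), %d nodes, atlas '%s'\n",
              length(x$matrices), sum(x$scores$synthetic),
              n_nodes(x$matrices[[1L]]), x$atlas_name))
  cat(sprintf("  score: mean %.2f, sd %.2f\n",
              mean(x$scores$score), stats::sd(x$scores$score)))
  invisible(x)
}

#' @export
length.connectome_dataset <- function(x) length(x$matrices)

#' Subset a connectome dataset by sample index
#'
#' @param x a `connectome_dataset`.
#' @param i integer or logical index over samples.
#' @param ... ignored.
#' @export
`[.connectome_dataset` <- function(x, i, ...) {
  connectome_dataset(x$matrices[i], x$scores[i, , drop = FALSE],
                     atlas_name = x$atlas_name)
}

#' Stack a dataset's edge vectors into a feature matrix
#'
#' @param d a `connectome_dataset`.
#' @return numeric matrix, one row per subject, one column per lower-triangle
#'   edge in the package's fixed ordering.
#' @export
edge_matrix <- function(d) {
  t(vapply(d$matrices, function(m) as.numeric(vectorize_lower_triangle(m)),
           numeric(n_nodes(d$matrices[[1L]]) *
                     (n_nodes(d$matrices[[1L]]) - 1) / 2)))
}

#' Read a connectome dataset from matrix files and a scores table
#'
#' Each matrix file is a plain delimited square numeric grid (comma or
#' whitespace separated, no header). The scores table is a CSV with header
#' columns `subject_id,score` (and optionally `synthetic`); sample order
#' follows the table. `matrix_paths` may be named by subject id; unnamed
#' paths are matched to subjects by file basename (minus extension), and
#' failing that by position.
#'
#' @param matrix_paths character vector of matrix file paths.
#' @param scores_table path to the scores CSV.
#' @param atlas_name parcellation label stored on the dataset.
#' @return a `connectome_dataset`.
#' @export
load_dataset <- function(matrix_paths, scores_table, atlas_name = "custom") {
  scores <- utils::read.csv(scores_table, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "score") %in% names(scores)))
    stop("scores table needs columns subject_id and score", call. = FALSE)
  scores$subject_id <- as.character(scores$subject_id)
  ids <- names(matrix_paths)
  if (is.null(ids) || !all(nzchar(ids)))
    ids <- sub("\\.[^.]*$", "", basename(matrix_paths))
  if (!all(scores$subject_id %in% ids)) {
    if (length(matrix_paths) == nrow(scores) && anyDuplicated(ids) == 0 &&
        !any(scores$subject_id %in% ids)) {
      ids <- scores$subject_id  # positional match
    } else {
      miss <- setdiff(scores$subject_id, ids)
      stop("no matrix file for subject_id: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  names(matrix_paths) <- ids
  mats <- lapply(scores$subject_id, function(sid) {
    p <- matrix_paths[[sid]]
    if (!file.exists(p))
      stop(sprintf("matrix file for subject '%s' not found: %s", sid, p),
           call. = FALSE)
    df <- tryCatch(
      utils::read.table(p, header = FALSE,
                        sep = if (grepl(",", readLines(p, n = 1L))) "," else ""),
      error = function(e) stop(sprintf("cannot parse '%s': %s", p,
                                       conditionMessage(e)), call. = FALSE))
    w <- as.matrix(df)
    if (!is.numeric(w))
      stop(sprintf("non-numeric cell in '%s'", p), call. = FALSE)
    tryCatch(connectivity_matrix(unname(w)),
             error = function(e) stop(sprintf("subject '%s': %s", sid,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  connectome_dataset(mats, scores, atlas_name = atlas_name)
}

#' Write a connectome dataset to a directory
#'
#' Writes one full-precision CSV matrix per subject, a `scores.csv`, and a
#' JSON manifest mapping subject ids to files. The on-disk form round-trips:
#' `load_dataset()` on the manifest's files reproduces the scores exactly and
#' the weights to within 1e-12 relative error.
#'
#' @param d a `connectome_dataset`.
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @seealso [read_dataset()]
#' @export
save_dataset <- function(d, out_dir) {
  stopifnot(inherits(d, "connectome_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  files <- character(length(d$matrices))
  for (k in seq_along(d$matrices)) {
    fn <- paste0("matrix_", gsub("[^A-Za-z0-9_.-]", "_",
                                 d$scores$subject_id[k]), ".csv")
    files[k] <- fn
    m <- as_weight_matrix(d$matrices[[k]])
    lines <- apply(m, 1L, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = ","))
    writeLines(lines, file.path(out_dir, fn))
  }
  # full-precision scores so the round trip is bit-exact
  sc <- d$scores
  sc$score <- formatC(sc$score, format = "g", digits = 17)
  utils::write.csv(sc, file.path(out_dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(format = "tggan-connectome-dataset",
                   atlas_name = d$atlas_name,
                   n_nodes = n_nodes(d$matrices[[1L]]),
                   node_labels = node_labels(d$matrices[[1L]]),
                   scores = "scores.csv",
                   subjects = stats::setNames(as.list(files),
                                              d$scores$subject_id))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}

#' Read a dataset previously written by [save_dataset()]
#'
#' @param dir directory containing `manifest.json`.
#' @return a `connectome_dataset`.
#' @export
read_dataset <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  paths <- stats::setNames(file.path(dir, unlist(man$subjects)),
                           names(man$subjects))
  d <- load_dataset(paths, file.path(dir, man$scores),
                    atlas_name = man$atlas_name)
  if (!is.null(man$node_labels))
    d$matrices <- lapply(d$matrices, function(m) {
      attr(m, "node_labels") <- as.character(man$node_labels)
      m
    })
  d
}

# evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
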