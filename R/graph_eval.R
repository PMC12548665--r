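#' Binarize a weighted network at an edge-density threshold
#'
#' Keeps the top `floor(density * E)` strongest of the `E = n(n-1)/2`
#' undirected edges (set to 1) and zeroes the rest. Ties at the cut are
#' broken deterministically by (weight descending, row ascending, column
#' ascending) over the package's lower-triangle edge ordering. Because the
#' rule is rank-based, the result is invariant to uniform rescaling of the
#' weights.
#'
#' @param m a `connectivity_matrix` (weighted).
#' @param density fraction of edges to keep, in (0, 1].
#' @return a binary `connectivity_matrix`.
#' @export
binarize_by_density <- function(m, density) {
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("'density' must be in (0, 1]", call. = FALSE)
  if (!inherits(m, "connectivity_matrix"))
    m <- connectivity_matrix(as.matrix(m))
  v <- as.numeric(vectorize_lower_triangle(m))
  E <- length(v)
  keep_n <- floor(density * E)
  pairs <- edge_index_pairs(n_nodes(m))
  ord <- order(-v, pairs[, 1L], pairs[, 2L])
  b <- numeric(E)
  b[ord[seq_len(keep_n)]] <- 1
  matricize(b, node_labels = node_labels(m))
}

as_igraph <- function(g) {
  w <- as_weight_matrix(g)
  igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                      weighted = NULL, diag = FALSE)
}

#' Graph-theory metrics of a binarized connectome
#'
#' Computes the six measures used to compare acquired and synthesized
#' networks: degree (connectivity strength on a binarized graph),
#' betweenness centrality (shortest-path based; normalized to `[0, 1]` by
#' `2 / ((n-1)(n-2))` when `normalize = TRUE`), local clustering
#' coefficient (triangle density around each node; 0 for degree < 2),
#' local efficiency, modularity (greedy agglomerative community detection,
#' resolution 1), and global efficiency (mean inverse shortest-path length
#' over all pairs; unreachable pairs contribute 0, so disconnected graphs
#' are handled without special-casing). Nodal measures are returned per
#' node together with their across-node means.
#'
#' @param g a binary `connectivity_matrix` (output of
#'   [binarize_by_density()]).
#' @param normalize normalize betweenness to `[0, 1]`.
#' @return list with per-node vectors `degree`, `betweenness`,
#'   `clustering`, `local_efficiency`; scalars `modularity`,
#'   `global_efficiency`; and `nodal_means`.
#' @export
graph_metrics <- function(g, normalize = TRUE) {
  w <- as_weight_matrix(as.matrix(g))
  if (!all(w %in% c(0, 1)))
    stop("input must be binary; use binarize_by_density() first",
         call. = FALSE)
  ig <- as_igraph(g)
  btw <- igraph::betweenness(ig, directed = FALSE, normalized = normalize)
  cc <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  # local efficiency in the brain-connectivity-toolbox sense: global
  # efficiency of the subgraph induced by each node's neighbors (igraph's
  # own local_efficiency() lets paths leave the neighborhood, a different
  # convention)
  leff <- vapply(seq_len(nrow(w)), function(v) {
    nb <- which(w[v, ] > 0)
    if (length(nb) < 2) return(0)
    igraph::global_efficiency(
      igraph::induced_subgraph(ig, nb), directed = FALSE)
  }, 1)
  mod <- if (igraph::ecount(ig) == 0) 0 else {
    memb <- igraph::membership(igraph::cluster_fast_greedy(ig))
    igraph::modularity(ig, memb)
  }
  geff <- if (igraph::ecount(ig) == 0) 0 else
    igraph::global_efficiency(ig, directed = FALSE)
  nodal <- list(degree = as.numeric(igraph::degree(ig)),
                betweenness = as.numeric(btw),
                clustering = as.numeric(cc),
                local_efficiency = as.numeric(leff))
  c(nodal,
    list(modularity = mod, global_efficiency = geff,
         nodal_means = vapply(nodal, mean, 1)))
}

#' Node strength of a weighted connectome
#'
#' Weighted counterpart of degree: the sum of each node's incident edge
#' weights on the unthresholded matrix.
#'
#' @param m a `connectivity_matrix`.
#' @export
node_strength <- function(m) rowSums(as_weight_matrix(as.matrix(m)))

#' Kullback-Leibler divergence between two metric distributions
#'
#' Estimates `KL(P_acquired || P_synthesized)` from samples: Gaussian kernel
#' density estimates with Silverman bandwidth are evaluated on a common
#' 512-point grid spanning both samples (plus three bandwidths of margin),
#' floored at 1e-12, renormalized, and summed discretely. Zero-variance
#' inputs fall back to a small bandwidth floor instead of failing. The
#' estimate is non-negative up to discretization and is exactly 0 for
#' identical inputs.
#'
#' @param acquired,synthesized numeric vectors (>= 5 values each).
#' @param n_grid number of grid points.
#' @return scalar KL divergence estimate (nats).
#' @export
metric_kl <- function(acquired, synthesized, n_grid = 512L) {
  x <- as.numeric(acquired); y <- as.numeric(synthesized)
  if (length(x) < 5 || length(y) < 5)
    stop("need at least 5 values per distribution", call. = FALSE)
  bw_of <- function(v) {
    if (stats::sd(v) == 0) max(1e-6, 1e-3 * max(1, abs(mean(v))))
    else stats::bw.nrd0(v)
  }
  bx <- bw_of(x); by <- bw_of(y)
  lo <- min(x, y) - 3 * max(bx, by)
  hi <- max(x, y) + 3 * max(bx, by)
  p <- stats::density(x, bw = bx, from = lo, to = hi, n = n_grid)$y
  q <- stats::density(y, bw = by, from = lo, to = hi, n = n_grid)$y
  p <- pmax(p, 1e-12); q <- pmax(q, 1e-12)
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Cohen's d between acquired and synthesized metric values
#'
#' Standardized mean difference with the sign convention
#' synthesized minus acquired. The paired form (default, matching a
#' per-subject reconstruction design) divides the mean within-pair
#' difference by the SD of the differences; the unpaired form uses the
#' pooled SD. When every paired difference is zero the effect is 0 by
#' convention; any other zero-SD case is an error.
#'
#' @param acquired,synthesized numeric vectors (equal length when paired).
#' @param paired use the paired form.
#' @export
cohens_d <- function(acquired, synthesized, paired = TRUE) {
  x <- as.numeric(acquired); y <- as.numeric(synthesized)
  if (paired) {
    if (length(x) != length(y))
      stop("paired inputs must have equal length", call. = FALSE)
    dd <- y - x
    if (all(dd == 0)) return(0)
    s <- stats::sd(dd)
    if (s == 0) stop("zero SD of paired differences", call. = FALSE)
    mean(dd) / s
  } else {
    nx <- length(x); ny <- length(y)
    sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
                 (nx + ny - 2))
    if (identical(x, y) || (mean(y) == mean(x) && sp == 0)) return(0)
    if (sp == 0) stop("zero pooled SD", call. = FALSE)
    (mean(y) - mean(x)) / sp
  }
}

#' Average elementwise difference between matched datasets
#'
#' Mean over subjects of `acquired - synthesized`, i.e. the average residual
#' connectivity the generator fails to reproduce (positive entries =
#' under-generated connections).
#'
#' @param acquired,synthesized `connectome_dataset`s with the same subjects
#'   in the same order.
#' @return symmetric numeric matrix.
#' @export
mean_difference_matrix <- function(acquired, synthesized) {
  stopifnot(inherits(acquired, "connectome_dataset"),
            inherits(synthesized, "connectome_dataset"))
  if (length(acquired$matrices) != length(synthesized$matrices))
    stop("datasets must contain the same subjects in the same order",
         call. = FALSE)
  n <- n_nodes(acquired$matrices[[1L]])
  acc <- matrix(0, n, n)
  for (k in seq_along(acquired$matrices))
    acc <- acc + (as_weight_matrix(acquired$matrices[[k]]) -
                    as_weight_matrix(synthesized$matrices[[k]]))
  acc / length(acquired$matrices)
}

average_matrix <- function(d) {
  n <- n_nodes(d$matrices[[1L]])
  acc <- matrix(0, n, n)
  for (m in d$matrices) acc <- acc + as_weight_matrix(m)
  connectivity_matrix(acc / length(d$matrices),
                      node_labels = node_labels(d$matrices[[1L]]))
}

#' Fidelity report: how faithfully do synthesized connectomes match?
#'
#' Runs the two evaluation pipelines over a grid of edge densities.
#' The averaged-matrix pipeline averages each dataset, binarizes the
#' averages at each density, and compares the nodal distributions of
#' degree, betweenness and clustering via KL divergence. The per-matrix
#' pipeline binarizes every subject's matrix, computes mean betweenness,
#' mean clustering, modularity, global efficiency and mean local efficiency
#' per matrix, and summarizes acquired-vs-synthesized differences as paired
#' Cohen's d per density.
#'
#' @param acquired,synthesized matched `connectome_dataset`s (same subjects,
#'   same order; typically `synthesized` holds the per-subject
#'   reconstructions).
#' @param densities edge-density grid.
#' @return object of class `"fidelity_report"`: `mean_difference_matrix`,
#'   `kl` (density x metric data frame), and `cohens_d` (density x measure
#'   data frame).
#' @export
fidelity_report <- function(acquired, synthesized,
                            densities = seq(0.05, 0.25, by = 0.05)) {
  mdm <- mean_difference_matrix(acquired, synthesized)
  avg_a <- average_matrix(acquired)
  avg_s <- average_matrix(synthesized)
  kl <- do.call(rbind, lapply(densities, function(dn) {
    ba <- graph_metrics(binarize_by_density(avg_a, dn))
    bs <- graph_metrics(binarize_by_density(avg_s, dn))
    data.frame(density = dn,
               strength = metric_kl(ba$degree, bs$degree),
               betweenness = metric_kl(ba$betweenness, bs$betweenness),
               clustering = metric_kl(ba$clustering, bs$clustering))
  }))
  per_matrix <- function(d, dn) {
    vals <- lapply(d$matrices, function(m)
      graph_metrics(binarize_by_density(m, dn)))
    data.frame(
      betweenness = vapply(vals, function(v) mean(v$betweenness), 1),
      clustering = vapply(vals, function(v) mean(v$clustering), 1),
      modularity = vapply(vals, function(v) v$modularity, 1),
      global_efficiency = vapply(vals, function(v) v$global_efficiency, 1),
      local_efficiency = vapply(vals, function(v) mean(v$local_efficiency), 1))
  }
  cd <- do.call(rbind, lapply(densities, function(dn) {
    va <- per_matrix(acquired, dn)
    vs <- per_matrix(synthesized, dn)
    row <- lapply(names(va), function(nm) cohens_d(va[[nm]], vs[[nm]],
                                                   paired = TRUE))
    names(row) <- names(va)
    cbind(data.frame(density = dn), as.data.frame(row))
  }))
  structure(list(mean_difference_matrix = mdm, kl = kl, cohens_d = cd,
                 densities = densities),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("Synthesis fidelity report\n")
  cat(sprintf("  mean |difference| per edge: %.4g\n",
              mean(abs(x$mean_difference_matrix))))
  cat("  KL divergence (acquired || synthesized), averaged-matrix pipeline:\n")
  print(x$kl, row.names = FALSE, digits = 3)
  cat("  Paired Cohen's d (synthesized - acquired), per-matrix pipeline:\n")
  print(x$cohens_d, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Serialize / restore a fidelity report
#'
#' @param report a `fidelity_report`.
#' @param path JSON file path.
#' @export
write_fidelity_report <- function(report, path) {
  stopifnot(inherits(report, "fidelity_report"))
  obj <- list(mean_difference_matrix = report$mean_difference_matrix,
              kl = report$kl, cohens_d = report$cohens_d,
              densities = report$densities)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fidelity_report
#' @export
read_fidelity_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_difference_matrix = as.matrix(obj$mean_difference_matrix),
                 kl = as.data.frame(obj$kl),
                 cohens_d = as.data.frame(obj$cohens_d),
                 densities = as.numeric(obj$densities)),
            class = "fidelity_report")
}
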