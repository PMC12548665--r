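#' Configuration for the synthetic connectome generator
#'
#' The generator emulates the study conditions the package targets: a cohort
#' of around one hundred subjects, a sparse non-negative symmetric structural
#' backbone shared across the group with two-block community structure, and a
#' continuous cognitive score (default mean 419.2, SD 40.9, the scale of a
#' summed NIH-Toolbox fluid-intelligence composite) linearly encoded in a
#' planted subset of edges plus half-normal edge noise.
#'
#' @param n_subjects number of subjects.
#' @param n_nodes number of regions (>= 6 so two communities remain
#'   non-degenerate).
#' @param score_mean,score_sd mean and SD of the simulated cognitive score.
#' @param n_signal_edges number of backbone edges carrying the score
#'   signal; defaults to about 9% of all possible edges (40 edges at 30
#'   nodes).
#' @param signal_strength edge-weight change per score SD on a signal edge
#'   (weight units); 0 plants no signal.
#' @param backbone_density fraction of all possible edges present in the
#'   group backbone, in (0, 1].
#' @param noise_sd scale of the half-normal subject-level edge noise.
#' @param global_strength_sd SD of the per-subject multiplicative
#'   global-strength factor (overall connectivity differs across subjects
#'   independently of the score; this factor is the dominant coherent
#'   variance component in real structural connectomes, so it keeps the
#'   planted score signal from being the leading principal component).
#' @param seed integer seed; generation is a pure function of the config,
#'   including this seed.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(n_subjects = 108, n_nodes = 30,
                         score_mean = 419.2, score_sd = 40.9,
                         n_signal_edges = NULL, signal_strength = 0.12,
                         backbone_density = 0.3, noise_sd = 0.5,
                         global_strength_sd = 0.15, seed = 1L) {
  E <- n_nodes * (n_nodes - 1) / 2
  if (is.null(n_signal_edges)) n_signal_edges <- max(1L, round(0.092 * E))
  stopifnot(n_subjects >= 2, n_nodes >= 6, score_sd > 0,
            n_signal_edges >= 1, backbone_density > 0, backbone_density <= 1,
            noise_sd >= 0, global_strength_sd >= 0, global_strength_sd < 1)
  if (n_signal_edges > E)
    stop("more signal edges than edges exist", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_nodes = as.integer(n_nodes),
                 score_mean = score_mean, score_sd = score_sd,
                 n_signal_edges = as.integer(n_signal_edges),
                 signal_strength = signal_strength,
                 backbone_density = backbone_density,
                 noise_sd = noise_sd,
                 global_strength_sd = global_strength_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# row-major lower-triangle (i, j) pairs matching vectorize_lower_triangle()
edge_index_pairs <- function(n) {
  i <- rep(2:n, times = 1:(n - 1))
  j <- unlist(lapply(2:n, function(k) 1:(k - 1)))
  cbind(i = i, j = j)
}

#' Generate a synthetic connectome dataset with a planted score signal
#'
#' Builds a fixed group backbone (sparse, symmetric, non-negative, two
#' communities with denser within- than between-block connectivity), draws
#' i.i.d. normal scores, and forms each subject's matrix as
#' `g_s * (backbone + slope * z(score) on the signal edges) + half-normal
#' noise` on the backbone support, clipped at zero, where `g_s` is the
#' subject's global-strength factor (`Normal(1, global_strength_sd)`,
#' truncated at 0.2). Signal edges receive an elevated backbone weight so
#' the linear score-edge relation survives clipping. Everything is drawn
#' inside an isolated RNG stream seeded from `cfg$seed`, so the same config
#' always yields a bit-identical dataset.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `data` (a [connectome_dataset()]) and
#'   `ground_truth` (signal edge indices into the package edge ordering,
#'   per-edge slopes, the backbone edge vector, and the config).
#' @export
generate_connectomes <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_nodes
  E <- n * (n - 1) / 2
  with_seed(cfg$seed, {
    pairs <- edge_index_pairs(n)
    block <- c(rep(1L, ceiling(n / 2)), rep(2L, floor(n / 2)))
    within <- block[pairs[, 1L]] == block[pairs[, 2L]]
    # within-block edges 4x more likely than between-block, overall density fixed
    p_out <- cfg$backbone_density * E / (4 * sum(within) + sum(!within))
    p_in <- min(4 * p_out, 1)
    keep <- stats::runif(E) < ifelse(within, p_in, p_out)
    support <- which(keep)
    if (length(support) < cfg$n_signal_edges)
      stop(sprintf(
        "infeasible config: %d signal edges requested but backbone has only %d edges",
        cfg$n_signal_edges, length(support)), call. = FALSE)
    template <- numeric(E)
    template[support] <- stats::rgamma(length(support), shape = 2, rate = 2)
    signal_edges <- sort(sample(support, cfg$n_signal_edges))
    slopes <- cfg$signal_strength *
      stats::runif(cfg$n_signal_edges, 0.5, 1.5) *
      sample(c(-1, 1), cfg$n_signal_edges, replace = TRUE)
    # headroom so slope * z never drives a signal edge negative (|z| <~ 4)
    template[signal_edges] <- template[signal_edges] + 0.5 + 4.5 * abs(slopes)
    y <- stats::rnorm(cfg$n_subjects, cfg$score_mean, cfg$score_sd)
    z <- as.numeric(scale(y))
    gs <- pmax(stats::rnorm(cfg$n_subjects, 1, cfg$global_strength_sd), 0.2)
    mats <- vector("list", cfg$n_subjects)
    for (s in seq_len(cfg$n_subjects)) {
      v <- template
      v[signal_edges] <- v[signal_edges] + slopes * z[s]
      v <- gs[s] * v
      if (cfg$noise_sd > 0)
        v[support] <- v[support] +
          abs(stats::rnorm(length(support), 0, cfg$noise_sd))
      mats[[s]] <- matricize(pmax(v, 0))
    }
    scores <- data.frame(subject_id = sprintf("sub-%03d", seq_len(cfg$n_subjects)),
                         score = y, synthetic = FALSE)
    list(data = connectome_dataset(mats, scores, atlas_name = "synthetic"),
         ground_truth = list(signal_edges = signal_edges, slopes = slopes,
                             backbone = template, support = support,
                             config = cfg))
  })
}

# flat index of edge (i, j), i > j, in the row-major lower-triangle ordering
edge_flat_index <- function(i, j, n) {
  ii <- pmax(i, j); jj <- pmin(i, j)
  (ii - 1) * (ii - 2) / 2 + jj
}

#' Remap generator ground truth after a node permutation
#'
#' If every matrix in a generated dataset is permuted with
#' [reorder_nodes()], the planted edges live at new flat positions; this
#' remaps the ground-truth edge indices (and reorders the slopes to match)
#' so [oracle_predictability()] refers to the same physical connections.
#'
#' @param ground_truth generator ground-truth list.
#' @param perm the permutation given to [reorder_nodes()].
#' @export
reorder_ground_truth <- function(ground_truth, perm) {
  n <- ground_truth$config$n_nodes
  pos <- order(perm)  # pos[old node] = new index
  pairs <- edge_index_pairs(n)
  remap <- function(idx) {
    i <- pos[pairs[idx, 1L]]; j <- pos[pairs[idx, 2L]]
    edge_flat_index(i, j, n)
  }
  new_idx <- remap(ground_truth$signal_edges)
  o <- order(new_idx)
  ground_truth$signal_edges <- new_idx[o]
  ground_truth$slopes <- ground_truth$slopes[o]
  ground_truth$support <- sort(remap(ground_truth$support))
  ground_truth$backbone <- {
    b <- numeric(length(ground_truth$backbone))
    b[remap(seq_along(ground_truth$backbone))] <- ground_truth$backbone
    b
  }
  ground_truth
}

#' Correlation between the score and the planted linear read-out
#'
#' Computes the Pearson correlation between the cognitive score and the
#' ground-truth read-out (slope-weighted sum of the planted signal edges).
#' It is the predictability ceiling for any learned linear predictor on this
#' dataset: noiseless generation gives r = 1, and a zero-strength signal
#' gives a null-distributed r.
#'
#' @param d a `connectome_dataset` produced by [generate_connectomes()] (or a
#'   subset / node-permuted version of it with matching edge count).
#' @param ground_truth the generator's ground-truth list.
#' @return Pearson correlation (scalar).
#' @export
oracle_predictability <- function(d, ground_truth) {
  X <- edge_matrix(d)
  readout <- X[, ground_truth$signal_edges, drop = FALSE] %*%
    ground_truth$slopes
  if (stats::sd(readout) == 0 || stats::sd(d$scores$score) == 0) return(0)
  stats::cor(as.numeric(readout), d$scores$score)
}
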