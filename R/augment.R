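#' Score-adjacent neighbor pairs
#'
#' Sorts the samples by cognitive score (stable tie-break on subject id) and
#' returns the `N - 1` consecutive pairs of original sample indices. These
#' are the interpolation endpoints for augmentation: neighbors in score are
#' assumed to vary approximately linearly, so convex combinations of their
#' latent codes and scores are meaningful.
#'
#' @param d a `connectome_dataset` with at least two samples.
#' @return two-column integer matrix (`i`, `j`), `i` the lower-scored member.
#' @export
neighbor_pairs <- function(d) {
  stopifnot(inherits(d, "connectome_dataset"))
  N <- length(d$matrices)
  if (N < 2) stop("need at least two samples to form pairs", call. = FALSE)
  ord <- order(d$scores$score, d$scores$subject_id)
  cbind(i = ord[-N], j = ord[-1L])
}

#' Synthesize one sample by latent interpolation
#'
#' Encodes two samples, forms the convex latent combination
#' `z = eps * D(X_i) + (1 - eps) * D(X_j)`, decodes it to a connectivity
#' matrix, and pairs it with the identically interpolated score
#' `y = eps * y_i + (1 - eps) * y_j`. `eps = 1` reproduces sample `i`'s
#' latent code and score exactly, `eps = 0` sample `j`'s. Encoding and
#' decoding run with dropout off.
#'
#' @param model a fitted [tg_gan()] model.
#' @param d a `connectome_dataset`.
#' @param i,j sample indices in `d`.
#' @param eps interpolation coefficient in `[0, 1]`.
#' @return list with `matrix` (a `connectivity_matrix`), `score`, and the
#'   latent code `z`.
#' @export
interpolate_pair <- function(model, d, i, j, eps) {
  stopifnot(inherits(model, "tg_gan"), inherits(d, "connectome_dataset"),
            eps >= 0, eps <= 1, i != j)
  n <- n_nodes(d$matrices[[1L]])
  if (n != model$n_nodes)
    stop("node-count mismatch between model and data", call. = FALSE)
  zi <- nn_forward(model$encoder, as_weight_matrix(d$matrices[[i]]))$out
  zj <- nn_forward(model$encoder, as_weight_matrix(d$matrices[[j]]))$out
  z <- eps * zi + (1 - eps) * zj
  m <- matricize(nn_forward(model$decoder, z)$out,
                 node_labels = model$node_labels)
  list(matrix = m,
       score = eps * d$scores$score[i] + (1 - eps) * d$scores$score[j],
       z = z)
}

#' Augment a dataset by latent-space interpolation
#'
#' Synthesizes new `(matrix, score)` pairs between score-adjacent samples.
#' In `k` mode every one of the `N - 1` neighbor pairs contributes `k`
#' samples at the interior grid `eps = t / (k + 1)`, `t = 1..k`, giving
#' `N + k (N - 1)` samples in total (75 real subjects become 149 at
#' `k = 1` and 371 at `k = 4`). In `target_total` mode the `m - N` new
#' samples are spread as evenly as possible across pairs, round-robin in
#' sorted order, with the same equally spaced interior grid within each
#' pair. Endpoints `eps` of 0 and 1 are never used (they would duplicate
#' real samples). Originals are retained bit-identically; synthesized
#' samples are flagged `synthetic = TRUE` and never enter validation or
#' test folds downstream.
#'
#' @param d a `connectome_dataset` of real samples.
#' @param model a fitted [tg_gan()] model.
#' @param k synthesized samples per neighbor pair (mutually exclusive with
#'   `target_total`).
#' @param target_total desired total size (> number of real samples).
#' @return a `connectome_dataset` of the originals plus the synthesized
#'   samples.
#' @export
augment <- function(d, model, k = NULL, target_total = NULL) {
  stopifnot(inherits(d, "connectome_dataset"), inherits(model, "tg_gan"))
  if (any(d$scores$synthetic))
    stop("augment() expects a dataset of real samples only", call. = FALSE)
  if (is.null(k) == is.null(target_total))
    stop("give exactly one of 'k' or 'target_total'", call. = FALSE)
  N <- length(d$matrices)
  pairs <- neighbor_pairs(d)
  n_pairs <- nrow(pairs)
  if (!is.null(k)) {
    stopifnot(k >= 1)
    counts <- rep(as.integer(k), n_pairs)
  } else {
    if (target_total <= N)
      stop("target_total must exceed the number of real samples",
           call. = FALSE)
    extra <- as.integer(target_total) - N
    counts <- rep(extra %/% n_pairs, n_pairs)
    rem <- extra %% n_pairs
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  }
  # encode every subject once; decode per synthesized sample
  Z <- encode_dataset(model, d)
  y <- d$scores$score
  ids <- d$scores$subject_id
  mats <- list(); scores <- numeric(0); sids <- character(0)
  for (p in seq_len(n_pairs)) {
    cp <- counts[p]
    if (cp == 0L) next
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    for (t in seq_len(cp)) {
      eps <- t / (cp + 1)
      z <- eps * Z[i, ] + (1 - eps) * Z[j, ]
      mats[[length(mats) + 1L]] <-
        matricize(nn_forward(model$decoder, z)$out,
                  node_labels = model$node_labels)
      scores <- c(scores, eps * y[i] + (1 - eps) * y[j])
      sids <- c(sids, sprintf("syn-%s-%s-%02d", ids[i], ids[j], t))
    }
  }
  out <- connectome_dataset(
    c(d$matrices, mats),
    data.frame(subject_id = c(ids, sids),
               score = c(y, scores),
               synthetic = c(d$scores$synthetic, rep(TRUE, length(sids)))),
    atlas_name = d$atlas_name)
  expected <- N + sum(counts)
  stopifnot(length(out$matrices) == expected)
  out
}

#' Simulate synthetic samples from a fitted model
#'
#' `simulate()` on a `tg_gan` model performs latent-interpolation
#' augmentation: `nsim` synthesized samples per neighbor pair of `data`.
#' Returns only the synthesized samples (use [augment()] to get the combined
#' dataset).
#'
#' @param object a fitted [tg_gan()] model.
#' @param nsim synthesized samples per neighbor pair.
#' @param seed ignored (interpolation is deterministic given the model).
#' @param data the real `connectome_dataset` to interpolate.
#' @param ... ignored.
#' @export
simulate.tg_gan <- function(object, nsim = 1, seed = NULL, data, ...) {
  aug <- augment(data, object, k = nsim)
  aug[aug$scores$synthetic]
}
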