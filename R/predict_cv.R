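#' Configuration for the repeated nested cross-validation benchmark
#'
#' Defaults follow the connectome-based prediction protocol the package
#' implements: 20 repeats of an outer 5-fold CV (100 models), an inner
#' 5-fold CV for hyperparameter tuning, ridge regression over the 16-point
#' penalty grid `2^n, n = -10..5`, or elastic net over
#' `2^(2n), n = -5..4` crossed with L1 ratios `0.2, 0.4, 0.6, 0.8, 1`.
#'
#' @param n_outer_folds,n_repeats,n_inner_folds CV geometry.
#' @param regressor `"ridge"` or `"elastic_net"`.
#' @param ridge_alphas ridge penalty grid.
#' @param enet_alphas elastic-net penalty grid.
#' @param enet_l1_ratios elastic-net L1/L2 mixing grid.
#' @param seed integer seed; all fold assignments derive from it.
#' @return list of class `"cv_config"`.
#' @export
cv_config <- function(n_outer_folds = 5L, n_repeats = 20L,
                      n_inner_folds = 5L,
                      regressor = c("ridge", "elastic_net"),
                      ridge_alphas = 2^(-10:5),
                      enet_alphas = 2^(2 * (-5:4)),
                      enet_l1_ratios = seq(0.2, 1, by = 0.2),
                      seed = 1L) {
  regressor <- match.arg(regressor)
  stopifnot(n_outer_folds >= 2, n_repeats >= 1, n_inner_folds >= 2,
            length(ridge_alphas) >= 1, length(enet_alphas) >= 1,
            length(enet_l1_ratios) >= 1)
  structure(list(n_outer_folds = as.integer(n_outer_folds),
                 n_repeats = as.integer(n_repeats),
                 n_inner_folds = as.integer(n_inner_folds),
                 regressor = regressor,
                 ridge_alphas = sort(ridge_alphas),
                 enet_alphas = sort(enet_alphas),
                 enet_l1_ratios = sort(enet_l1_ratios),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' Rank-interleaved train/test split
#'
#' Sorts samples by score (stable), ranks them `1..N`, and holds out every
#' `holdout_stride`-th rank starting at `holdout_offset` (default: ranks
#' 1, 4, 7, ...). Interleaving by rank keeps the score distributions of the
#' two partitions closely matched, which random splitting cannot guarantee
#' at small N.
#'
#' @param d a `connectome_dataset`.
#' @param holdout_stride keep 1 of every `holdout_stride` ranks out.
#' @param holdout_offset first held-out rank.
#' @return list of class `"split_plan"` with `discovery_ids`, `test_ids`
#'   (subject ids) and the corresponding index vectors `discovery_idx`,
#'   `test_idx`.
#' @export
rank_interleaved_split <- function(d, holdout_stride = 3L,
                                   holdout_offset = 1L) {
  stopifnot(inherits(d, "connectome_dataset"), holdout_stride >= 2,
            holdout_offset >= 1, holdout_offset <= holdout_stride)
  N <- length(d$matrices)
  if (N < holdout_stride)
    stop("fewer samples than the holdout stride", call. = FALSE)
  ord <- order(d$scores$score, d$scores$subject_id)
  ranks <- seq_len(N)
  held <- ord[(ranks - holdout_offset) %% holdout_stride == 0]
  kept <- setdiff(ord, held)
  structure(list(
    discovery_ids = d$scores$subject_id[sort(kept)],
    test_ids = d$scores$subject_id[sort(held)],
    discovery_idx = sort(kept), test_idx = sort(held),
    rule = sprintf("every rank r with (r - %d) %%%% %d == 0 held out",
                   holdout_offset, holdout_stride)),
    class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Rank-interleaved split: %d discovery / %d held out (%s)\n",
              length(x$discovery_idx), length(x$test_idx), x$rule))
  invisible(x)
}

# ---- model fitting ---------------------------------------------------------

standardize_fit <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  list(mu = mu, sd = sds)
}

standardize_apply <- function(X, st) sweep(sweep(X, 2L, st$mu), 2L, st$sd, "/")

# closed-form ridge path via one SVD: returns p x length(alphas) coefficients
# and intercepts, on the scale of the inputs given
ridge_path <- function(X, y, alphas) {
  mx <- colMeans(X)
  Xc <- sweep(X, 2L, mx)
  my <- mean(y)
  yc <- y - my
  sv <- svd(Xc)
  uty <- crossprod(sv$u, yc)
  W <- vapply(alphas, function(a)
    as.numeric(sv$v %*% (sv$d / (sv$d^2 + a) * uty)),
    numeric(ncol(X)))
  W <- matrix(W, ncol = length(alphas))
  b <- my - as.numeric(mx %*% W)
  list(W = W, b = b)
}

# hyperparameter grid as a data frame with columns alpha (and l1_ratio)
hyper_grid <- function(cfg) {
  if (cfg$regressor == "ridge")
    data.frame(alpha = cfg$ridge_alphas, l1_ratio = NA_real_)
  else
    expand.grid(alpha = cfg$enet_alphas, l1_ratio = cfg$enet_l1_ratios)
}

# Fit every grid point; returns W (p x G) and b (G).
# The elastic net follows the common convention
#   (1/2n) ||y - Xw||^2 + alpha * (l1 ||w||_1 + (1 - l1)/2 ||w||^2).
# glmnet solves this exactly only after y is standardized to unit
# (population) variance; the penalty then maps to
#   lambda = alpha l1 / s + alpha (1 - l1),  alpha_glmnet = alpha l1 / (s lambda)
# with coefficients rescaled by s afterwards.
fit_grid <- function(X, y, cfg, grid = hyper_grid(cfg)) {
  if (cfg$regressor == "ridge") {
    ridge_path(X, y, grid$alpha)
  } else {
    p <- ncol(X)
    W <- matrix(0, p, nrow(grid))
    b <- numeric(nrow(grid))
    n <- length(y)
    s <- sqrt(stats::var(y) * (n - 1) / n)
    if (!is.finite(s) || s == 0) s <- 1
    yt <- y / s
    for (r in seq_len(nrow(grid))) {
      a <- grid$alpha[r]; l1 <- grid$l1_ratio[r]
      lg <- a * l1 / s + a * (1 - l1)
      ag <- if (lg > 0) (a * l1 / s) / lg else 1
      path <- exp(seq(log(max(lg * 100, 1)), log(lg), length.out = 25))
      fit <- suppressWarnings(
        glmnet::glmnet(X, yt, alpha = ag, lambda = path,
                       standardize = FALSE, thresh = 1e-10, maxit = 1e6))
      cf <- as.numeric(glmnet::coef.glmnet(fit, s = lg))
      b[r] <- s * cf[1L]
      W[, r] <- s * cf[-1L]
    }
    list(W = W, b = b)
  }
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# z-score a vector across grid points; zero spread -> all zeros
zgrid <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

# inner-CV selection score: standardized mean correlation plus standardized
# inverse MAE across the hyperparameter grid
combine_grid_scores <- function(r_mean, mae_mean) {
  zgrid(r_mean) + zgrid(1 / mae_mean)
}

#' Inner cross-validated hyperparameter tuning
#'
#' For every grid point, runs a `n_inner_folds`-fold CV on the training
#' data (synthetic samples are confined to the inner training folds; only
#' real samples are used for inner validation), averages Pearson r and MAE
#' across folds, standardizes the mean-r and inverse-MAE vectors across the
#' grid, and picks the grid point maximizing their sum. Ties go to the
#' smaller penalty (then smaller L1 ratio). Constant predictions count as
#' r = 0.
#'
#' @param X standardized feature matrix (rows = training samples).
#' @param y scores.
#' @param synthetic logical flag per row.
#' @param cfg a [cv_config()].
#' @return list with `best` (one grid row) and the per-grid `table`.
#' @export
inner_tune <- function(X, y, synthetic = rep(FALSE, length(y)), cfg) {
  stopifnot(nrow(X) == length(y), length(synthetic) == length(y))
  real <- which(!synthetic)
  if (length(real) < cfg$n_inner_folds)
    stop("too few real samples for the inner folds", call. = FALSE)
  grid <- hyper_grid(cfg)
  G <- nrow(grid)
  folds <- sample(rep(seq_len(cfg$n_inner_folds),
                      length.out = length(real)))
  r_sum <- mae_sum <- numeric(G)
  for (f in seq_len(cfg$n_inner_folds)) {
    val <- real[folds == f]
    tr <- setdiff(seq_along(y), val)
    st <- standardize_fit(X[tr, , drop = FALSE])
    fit <- fit_grid(standardize_apply(X[tr, , drop = FALSE], st), y[tr],
                    cfg, grid)
    pred <- standardize_apply(X[val, , drop = FALSE], st) %*% fit$W
    pred <- sweep(pred, 2L, fit$b, "+")
    for (g in seq_len(G)) {
      r_sum[g] <- r_sum[g] + safe_cor(pred[, g], y[val])
      mae_sum[g] <- mae_sum[g] + mean(abs(pred[, g] - y[val]))
    }
  }
  tab <- grid
  tab$r_mean <- r_sum / cfg$n_inner_folds
  tab$mae_mean <- mae_sum / cfg$n_inner_folds
  tab$score <- combine_grid_scores(tab$r_mean, tab$mae_mean)
  pick <- order(-tab$score, tab$alpha, tab$l1_ratio)[1L]
  list(best = grid[pick, , drop = FALSE], table = tab)
}

#' Repeated nested cross-validation
#'
#' Runs `n_repeats` repetitions of an outer `n_outer_folds`-fold CV on the
#' real samples; each outer training fold (plus every synthetic sample, or
#' the output of `augmenter` applied to the fold's real samples) is tuned
#' with [inner_tune()] and refitted, and the model is validated on the
#' fold's real held-out samples. Synthetic samples never enter a
#' validation fold. All randomness derives from `cfg$seed`.
#'
#' @param d `connectome_dataset` (may already contain synthetic samples).
#' @param cfg a [cv_config()].
#' @param augmenter optional `function(dataset_of_real_training_samples)`
#'   returning an augmented `connectome_dataset`; incompatible with a
#'   pre-augmented `d`.
#' @return object of class `"cv_result"`: per-model `records` (repeat,
#'   fold, chosen hyperparameters, validation r and MAE), original-scale
#'   `weights` (models x edges) and `intercepts`, and the per-model
#'   training/validation subject ids for leakage auditing.
#' @export
repeated_nested_cv <- function(d, cfg = cv_config(), augmenter = NULL) {
  stopifnot(inherits(d, "connectome_dataset"), inherits(cfg, "cv_config"))
  if (!is.null(augmenter) && any(d$scores$synthetic))
    stop("give either a pre-augmented dataset or an augmenter, not both",
         call. = FALSE)
  X <- edge_matrix(d)
  y <- d$scores$score
  synth <- d$scores$synthetic
  ids <- d$scores$subject_id
  real <- which(!synth)
  if (length(real) < cfg$n_outer_folds * 2)
    stop("too few real samples for the outer folds", call. = FALSE)
  n_models <- cfg$n_repeats * cfg$n_outer_folds
  records <- vector("list", n_models)
  weights <- matrix(NA_real_, n_models, ncol(X))
  intercepts <- numeric(n_models)
  train_ids <- val_ids <- vector("list", n_models)
  with_seed(cfg$seed, {
    mi <- 0L
    for (rep_i in seq_len(cfg$n_repeats)) {
      fold_of <- sample(rep(seq_len(cfg$n_outer_folds),
                            length.out = length(real)))
      for (f in seq_len(cfg$n_outer_folds)) {
        mi <- mi + 1L
        val <- real[fold_of == f]
        if (length(val) < 2) stop("outer fold too small", call. = FALSE)
        tr_real <- setdiff(real, val)
        if (is.null(augmenter)) {
          tr <- c(tr_real, which(synth))
          Xtr <- X[tr, , drop = FALSE]
          ytr <- y[tr]
          syntr <- synth[tr]
          idstr <- ids[tr]
        } else {
          aug <- augmenter(d[tr_real])
          Xtr <- edge_matrix(aug)
          ytr <- aug$scores$score
          syntr <- aug$scores$synthetic
          idstr <- aug$scores$subject_id
        }
        stopifnot(!any(ids[val] %in% idstr[syntr]))
        tune <- inner_tune(Xtr, ytr, syntr, cfg)
        st <- standardize_fit(Xtr)
        fit <- fit_grid(standardize_apply(Xtr, st), ytr, cfg, tune$best)
        w_std <- fit$W[, 1L]
        w <- w_std / st$sd
        b <- fit$b[1L] - sum(st$mu * w)
        pred <- as.numeric(X[val, , drop = FALSE] %*% w) + b
        weights[mi, ] <- w
        intercepts[mi] <- b
        records[[mi]] <- data.frame(
          rep = rep_i, fold = f,
          alpha = tune$best$alpha, l1_ratio = tune$best$l1_ratio,
          val_r = safe_cor(pred, y[val]),
          val_constant = stats::sd(pred) == 0,
          val_mae = mean(abs(pred - y[val])))
        train_ids[[mi]] <- idstr
        val_ids[[mi]] <- ids[val]
      }
    }
  })
  structure(list(records = do.call(rbind, records), weights = weights,
                 intercepts = intercepts, train_ids = train_ids,
                 val_ids = val_ids, cfg = cfg,
                 n_nodes = n_nodes(d$matrices[[1L]])),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "Repeated nested CV (%s): %d models (%d repeats x %d folds)\n",
    x$cfg$regressor, nrow(x$records), x$cfg$n_repeats, x$cfg$n_outer_folds))
  cat(sprintf("  validation r: %.3f +/- %.3f | MAE: %.3f +/- %.3f\n",
              mean(x$records$val_r), stats::sd(x$records$val_r),
              mean(x$records$val_mae), stats::sd(x$records$val_mae)))
  invisible(x)
}

#' Out-of-sample evaluation of every CV model
#'
#' Applies each trained model to a fixed test set and reports per-model
#' Pearson r and RMSE plus their mean and SD. Synthetic samples are refused
#' in the test set; constant predictions are reported as r = 0 with a flag.
#'
#' @param models a `cv_result`.
#' @param test_data real-sample `connectome_dataset`, disjoint from
#'   training.
#' @return data frame (one row per model: `test_r`, `test_rmse`,
#'   `constant`) with a `summary` attribute holding the means and SDs.
#' @export
evaluate_test <- function(models, test_data) {
  stopifnot(inherits(models, "cv_result"),
            inherits(test_data, "connectome_dataset"))
  if (any(test_data$scores$synthetic))
    stop("test data must not contain synthetic samples", call. = FALSE)
  tr_all <- unique(unlist(models$val_ids))
  if (any(test_data$scores$subject_id %in% tr_all))
    stop("test data overlaps the cross-validated discovery samples",
         call. = FALSE)
  X <- edge_matrix(test_data)
  y <- test_data$scores$score
  preds <- X %*% t(models$weights)
  preds <- sweep(preds, 2L, models$intercepts, "+")
  out <- data.frame(
    model = seq_len(ncol(preds)),
    test_r = apply(preds, 2L, function(p) safe_cor(p, y)),
    test_rmse = apply(preds, 2L, function(p) sqrt(mean((p - y)^2))),
    constant = apply(preds, 2L, function(p) stats::sd(p) == 0))
  attr(out, "summary") <- c(
    r_mean = mean(out$test_r), r_sd = stats::sd(out$test_r),
    rmse_mean = mean(out$test_rmse), rmse_sd = stats::sd(out$test_rmse))
  out
}

#' Welch comparison of two accuracy distributions
#'
#' Screens each group once for values more than 3 SD from its mean, runs
#' Welch's unequal-variance two-sided t test on the survivors, and applies
#' a Bonferroni correction for `n_comparisons` tests. Identical groups give
#' t = 0, p = 1 by convention (the t statistic is undefined at zero
#' variance).
#'
#' @param group_a,group_b numeric accuracy vectors (>= 3 values each).
#' @param n_comparisons Bonferroni multiplier.
#' @return list: `t`, `df`, `p`, `p_adjusted`, `n_removed_a`,
#'   `n_removed_b`, group means after screening.
#' @export
compare_accuracy <- function(group_a, group_b, n_comparisons = 1L) {
  stopifnot(length(group_a) >= 3, length(group_b) >= 3, n_comparisons >= 1)
  screen <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(v)
    v[abs(v - m) <= 3 * s]
  }
  a <- screen(group_a); b <- screen(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("outlier screening emptied a group", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if ((va == 0 && vb == 0)) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                  p.value = 1)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf,
                  parameter = length(a) + length(b) - 2, p.value = 0)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic),
                parameter = unname(tt$parameter), p.value = tt$p.value)
  }
  list(t = res$statistic, df = res$parameter, p = res$p.value,
       p_adjusted = min(1, res$p.value * n_comparisons),
       n_removed_a = length(group_a) - length(a),
       n_removed_b = length(group_b) - length(b),
       mean_a = mean(a), mean_b = mean(b))
}

#' Reliability of edge weights across CV models
#'
#' Per edge: mean weight across the models and the percentile 95% CI
#' (2.5th to 97.5th) with its width. Narrow intervals indicate the models
#' agree on which connections carry predictive signal.
#'
#' @param models a `cv_result` (>= 2 models).
#' @return data frame: `edge`, node pair `i`/`j`, `mean`, `ci_low`,
#'   `ci_high`, `width`.
#' @export
weight_reliability <- function(models) {
  stopifnot(inherits(models, "cv_result"))
  W <- models$weights
  if (nrow(W) < 2) stop("need at least 2 models", call. = FALSE)
  qs <- apply(W, 2L, stats::quantile, probs = c(0.025, 0.975))
  pairs <- edge_index_pairs(models$n_nodes)
  data.frame(edge = seq_len(ncol(W)), i = pairs[, 1L], j = pairs[, 2L],
             mean = colMeans(W), ci_low = qs[1L, ], ci_high = qs[2L, ],
             width = qs[2L, ] - qs[1L, ])
}

#' Correlation between the leading principal component and a score
#'
#' Centers the latent matrix, fits a PCA on it, canonicalizes each
#' component's sign (the loading with the largest magnitude is made
#' positive, so the correlation's sign is deterministic), and returns the
#' two-dimensional projection together with the Pearson correlation (and
#' two-sided p value) between PC1 and the score.
#'
#' @param Z numeric matrix of latent coordinates (rows = samples).
#' @param y numeric score vector.
#' @return list: `projections` (N x 2), `r`, `p`, `var_explained`.
#' @export
pca_score_correlation <- function(Z, y) {
  stopifnot(is.matrix(Z), nrow(Z) == length(y), nrow(Z) >= 3)
  keep_sd <- apply(Z, 2L, stats::sd)
  if (all(keep_sd == 0)) stop("zero-variance latents", call. = FALSE)
  pc <- stats::prcomp(Z, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  for (cmp in seq_len(k)) {
    flip <- sign(pc$rotation[which.max(abs(pc$rotation[, cmp])), cmp])
    if (flip < 0) {
      pc$rotation[, cmp] <- -pc$rotation[, cmp]
      pc$x[, cmp] <- -pc$x[, cmp]
    }
  }
  pc1 <- pc$x[, 1L]
  if (stats::sd(pc1) == 0 || stats::sd(y) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(pc1, y)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  proj <- pc$x[, seq_len(k), drop = FALSE]
  list(projections = proj, r = r, p = p,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Latent-space PCA against the cognitive score
#'
#' Encodes a dataset with the trained encoder (dropout off), projects the
#' latent codes onto their first two principal components, and correlates
#' PC1 with the cognitive score. A task-guided model is expected to show a
#' much stronger PC1-score correlation on its training data than a plain
#' adversarial model. The PCA is fitted on the given subset only, so
#' training and validation sets get independent projections.
#'
#' @param model a fitted [tg_gan()] model.
#' @param d a `connectome_dataset` (N >= 3).
#' @return as [pca_score_correlation()].
#' @export
latent_pca <- function(model, d) {
  Z <- encode_dataset(model, d)
  pca_score_correlation(Z, d$scores$score)
}
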