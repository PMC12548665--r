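#' Training configuration for the adversarial models
#'
#' Optimization settings for [tg_gan()]. The defaults follow standard
#' practice for Wasserstein critics with gradient penalty: Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, learning rate `1e-4`, batch size 2,
#' penalty coefficient `gp_lambda = 10`, five critic updates per generator
#' update, and up to 2000 epochs with early stopping on the validation
#' regressor loss (triggered when the loss has not improved for `patience`
#' epochs, counted only after `warmup_epochs`). `task_alpha` weights the
#' regression loss in the combined objective; `task_alpha = 0` trains a
#' plain WGAN-GP with no regressor branch and no early stopping.
#'
#' @param learning_rate Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam momentum parameters.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param gp_lambda gradient-penalty coefficient.
#' @param task_alpha weight of the task-guided regression loss (>= 0).
#' @param critic_steps_per_gen critic updates per generator update.
#' @param patience early-stopping patience in epochs.
#' @param warmup_epochs epochs before the patience counter may fire.
#' @param seed integer seed controlling initialization, shuffling, dropout
#'   and penalty interpolation; a fixed seed makes training bit-reproducible.
#' @param regressor_loss_type `"rmse"` (root mean squared error, the default)
#'   or `"sum_squares"` (plain sum of squared errors).
#' @param checkpoint which parameters the fitted model keeps in task-guided
#'   mode: `"final"` (the state when training stopped, the default) or
#'   `"best"` (the best-validation-loss epoch). The validation regressor
#'   loss often bottoms out long before the generator can synthesize
#'   anything useful, so rolling back to that epoch tends to return an
#'   undertrained generator; early stopping itself is unaffected by this
#'   choice.
#' @param verbose print a progress line every `verbose` epochs (0 = quiet).
#' @return list of class `"gan_control"`.
#' @export
gan_control <- function(learning_rate = 1e-4, adam_beta1 = 0.9,
                        adam_beta2 = 0.999, batch_size = 2L,
                        max_epochs = 2000L, gp_lambda = 10,
                        task_alpha = 0.5, critic_steps_per_gen = 5L,
                        patience = 50L, warmup_epochs = 500L, seed = 1L,
                        regressor_loss_type = c("rmse", "sum_squares"),
                        checkpoint = c("final", "best"), verbose = 0L) {
  stopifnot(learning_rate > 0, adam_beta1 >= 0, adam_beta1 < 1,
            adam_beta2 >= 0, adam_beta2 < 1, batch_size >= 1,
            max_epochs >= 1, gp_lambda >= 0, task_alpha >= 0,
            critic_steps_per_gen >= 1, patience >= 1, warmup_epochs >= 0)
  structure(list(learning_rate = learning_rate, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), gp_lambda = gp_lambda,
                 task_alpha = task_alpha,
                 critic_steps_per_gen = as.integer(critic_steps_per_gen),
                 patience = as.integer(patience),
                 warmup_epochs = as.integer(warmup_epochs),
                 seed = as.integer(seed),
                 regressor_loss_type = match.arg(regressor_loss_type),
                 checkpoint = match.arg(checkpoint),
                 verbose = as.integer(verbose)),
            class = "gan_control")
}

#' Regression loss of the task-guided branch
#'
#' Root mean squared error between observed and predicted scores (the named
#' quantity the task-guided branch minimizes); a plain sum-of-squares variant
#' is available via `type = "sum_squares"`.
#'
#' @param y_obs,y_pred numeric vectors of equal, positive length.
#' @param type `"rmse"` or `"sum_squares"`.
#' @export
regressor_loss <- function(y_obs, y_pred, type = c("rmse", "sum_squares")) {
  type <- match.arg(type)
  if (!length(y_obs) || length(y_obs) != length(y_pred))
    stop("y_obs and y_pred must be non-empty and of equal length",
         call. = FALSE)
  sq <- (y_obs - y_pred)^2
  if (type == "rmse") sqrt(mean(sq)) else sum(sq)
}

as_matrix_batch <- function(x) {
  if (is.list(x)) lapply(x, as_weight_matrix)
  else if (is.matrix(x)) list(as_weight_matrix(x))
  else stop("batch must be a matrix or a list of matrices", call. = FALSE)
}

#' Wasserstein gradient penalty
#'
#' One-sided two-norm penalty enforcing 1-Lipschitz behavior of the critic:
#' samples `x_hat = u * x_real + (1 - u) * x_fake` with `u ~ Uniform(0,1)`
#' per pair, computes the critic's input gradient there by backpropagation,
#' and returns `mean((||grad||_2 - 1)^2)` over the batch. For a linear
#' critic with weight matrix `W` this equals `(||W||_F - 1)^2` exactly.
#' Evaluated with dropout off.
#'
#' @param critic a `brainnet_network` critic.
#' @param x_real,x_fake lists of equally sized square matrices (or single
#'   matrices), paired by position.
#' @return non-negative scalar penalty.
#' @export
gradient_penalty <- function(critic, x_real, x_fake) {
  xr <- as_matrix_batch(x_real)
  xf <- as_matrix_batch(x_fake)
  if (length(xr) != length(xf))
    stop("real and fake batches must have equal length", call. = FALSE)
  pen <- 0
  for (k in seq_along(xr)) {
    u <- stats::runif(1)
    xh <- u * xr[[k]] + (1 - u) * xf[[k]]
    fw <- nn_forward(critic, xh)
    g <- nn_backward(critic, fw, 1)$gin
    pen <- pen + (sqrt(sum(g^2)) - 1)^2
  }
  pen / length(xr)
}

#' Critic and generator adversarial losses
#'
#' `critic_loss()` returns the quantity the critic minimizes,
#' `mean(C(x_fake)) - mean(C(x_real)) + gp_lambda * penalty` (its negative is
#' the penalized Wasserstein objective the critic maximizes);
#' `generator_adv_loss()` returns `-mean(C(x_fake))`, the adversarial part of
#' the generator objective. Both evaluate the critic with dropout off.
#'
#' @inheritParams gradient_penalty
#' @param gp_lambda gradient-penalty coefficient.
#' @export
critic_loss <- function(critic, x_real, x_fake, gp_lambda = 10) {
  xr <- as_matrix_batch(x_real)
  xf <- as_matrix_batch(x_fake)
  cr <- vapply(xr, function(x) nn_forward(critic, x)$out, 1)
  cf <- vapply(xf, function(x) nn_forward(critic, x)$out, 1)
  if (any(!is.finite(c(cr, cf))))
    stop("non-finite critic output", call. = FALSE)
  pen <- if (gp_lambda > 0) gradient_penalty(critic, xr, xf) else 0
  mean(cf) - mean(cr) + gp_lambda * pen
}

#' @rdname critic_loss
#' @export
generator_adv_loss <- function(critic, x_fake) {
  xf <- as_matrix_batch(x_fake)
  -mean(vapply(xf, function(x) nn_forward(critic, x)$out, 1))
}

# ---- training internals ----------------------------------------------------

# one supervised step of the task regressor on already-synthesized matrices
regressor_update <- function(reg, st_r, xf, yz, control) {
  B <- length(xf)
  fg <- vector("list", B)
  yhat <- numeric(B)
  for (k in seq_len(B)) {
    fg[[k]] <- nn_forward(reg, xf[[k]], train = TRUE)
    yhat[k] <- fg[[k]]$out
  }
  if (control$regressor_loss_type == "rmse") {
    rl <- sqrt(mean((yz - yhat)^2))
    if (rl < 1e-12) return(list(reg = reg, state = st_r))
    dy <- (yhat - yz) / (B * rl)
  } else {
    dy <- 2 * (yhat - yz)
  }
  gr <- NULL
  for (k in seq_len(B))
    gr <- acc_grads(gr, nn_backward(reg, fg[[k]], dy[k])$grads, 1)
  up <- adam_step(reg, gr, st_r, control$learning_rate,
                  control$adam_beta1, control$adam_beta2)
  list(reg = up$net, state = up$state)
}

# critic minibatch update; returns new critic/adam state and the loss value
critic_update <- function(critic, st, enc, dec, xr, control, n) {
  B <- length(xr)
  xf <- lapply(xr, function(x) {
    z <- nn_forward(enc, x)$out
    edgevec_to_matrix(nn_forward(dec, z)$out, n)
  })
  gacc <- NULL
  cr <- cf <- numeric(B)
  for (k in seq_len(B)) {
    fr <- nn_forward(critic, xr[[k]], train = TRUE)
    cr[k] <- fr$out
    gacc <- acc_grads(gacc, nn_backward(critic, fr, 1)$grads, -1 / B)
    ff <- nn_forward(critic, xf[[k]], train = TRUE)
    cf[k] <- ff$out
    gacc <- acc_grads(gacc, nn_backward(critic, ff, 1)$grads, 1 / B)
  }
  pen <- 0
  if (control$gp_lambda > 0) {
    for (k in seq_len(B)) {
      u <- stats::runif(1)
      xh <- u * xr[[k]] + (1 - u) * xf[[k]]
      fh <- nn_forward(critic, xh, train = TRUE)
      g <- nn_backward(critic, fh, 1)$gin
      nk <- sqrt(sum(g * g))
      pen <- pen + (nk - 1)^2 / B
      if (nk > 1e-12) {
        # d penalty / d theta via a central difference of parameter
        # gradients along the unit input direction g / ||g||
        ghat <- g / nk
        h <- 1e-4 * (1 + sqrt(sum(xh * xh)) / n)
        coef <- control$gp_lambda * 2 * (nk - 1) / (B * 2 * h)
        fp <- nn_forward(critic, xh + h * ghat, train = TRUE,
                         masks = fh$masks)
        gacc <- acc_grads(gacc, nn_backward(critic, fp, 1)$grads, coef)
        fm <- nn_forward(critic, xh - h * ghat, train = TRUE,
                         masks = fh$masks)
        gacc <- acc_grads(gacc, nn_backward(critic, fm, 1)$grads, -coef)
      }
    }
  }
  upd <- adam_step(critic, gacc, st, control$learning_rate,
                   control$adam_beta1, control$adam_beta2)
  list(critic = upd$net, state = upd$state, xf = xf,
       loss = mean(cf) - mean(cr) + control$gp_lambda * pen)
}

# generator (+ regressor) minibatch update
generator_update <- function(enc, dec, reg, st_e, st_d, st_r, critic,
                             xr, yz, control, n) {
  B <- length(xr)
  fe <- fd <- fc <- fg <- vector("list", B)
  xf <- vector("list", B)
  yhat <- numeric(B)
  for (k in seq_len(B)) {
    fe[[k]] <- nn_forward(enc, xr[[k]], train = TRUE)
    fd[[k]] <- nn_forward(dec, fe[[k]]$out)
    xf[[k]] <- edgevec_to_matrix(fd[[k]]$out, n)
    fc[[k]] <- nn_forward(critic, xf[[k]])
    if (!is.null(reg)) {
      fg[[k]] <- nn_forward(reg, xf[[k]], train = TRUE)
      yhat[k] <- fg[[k]]$out
    }
  }
  adv <- -mean(vapply(fc, `[[`, 1, "out"))
  rloss <- 0
  dy <- numeric(B)
  if (!is.null(reg)) {
    if (control$regressor_loss_type == "rmse") {
      rloss <- sqrt(mean((yz - yhat)^2))
      if (rloss > 1e-12) dy <- (yhat - yz) / (B * rloss)
    } else {
      rloss <- sum((yz - yhat)^2)
      dy <- 2 * (yhat - yz)
    }
  }
  ge <- gd <- gr <- NULL
  for (k in seq_len(B)) {
    bc <- nn_backward(critic, fc[[k]], 1)
    dxf <- -bc$gin / B
    if (!is.null(reg)) {
      br <- nn_backward(reg, fg[[k]], control$task_alpha * dy[k])
      gr <- acc_grads(gr, br$grads, 1)
      dxf <- dxf + br$gin
    }
    dev <- matrix_grad_to_edgevec(dxf)
    bd <- nn_backward(dec, fd[[k]], dev, input_was_matrix = FALSE)
    gd <- acc_grads(gd, bd$grads, 1)
    be <- nn_backward(enc, fe[[k]], bd$gin)
    ge <- acc_grads(ge, be$grads, 1)
  }
  ue <- adam_step(enc, ge, st_e, control$learning_rate,
                  control$adam_beta1, control$adam_beta2)
  ud <- adam_step(dec, gd, st_d, control$learning_rate,
                  control$adam_beta1, control$adam_beta2)
  out <- list(enc = ue$net, dec = ud$net, st_e = ue$state, st_d = ud$state,
              adv = adv, rloss = rloss, reg = reg, st_r = st_r)
  if (!is.null(reg)) {
    ur <- adam_step(reg, gr, st_r, control$learning_rate,
                    control$adam_beta1, control$adam_beta2)
    out$reg <- ur$net
    out$st_r <- ur$state
  }
  out
}

# dropout-off pass over a whole dataset: reconstruction error and, when a
# regressor is present, the regression loss on the standardized score scale
eval_pass <- function(enc, dec, reg, X, yz, n, loss_type) {
  recon <- 0
  yhat <- numeric(length(X))
  for (k in seq_along(X)) {
    z <- nn_forward(enc, X[[k]])$out
    xf <- edgevec_to_matrix(nn_forward(dec, z)$out, n)
    recon <- recon + sqrt(sum((X[[k]] - xf)^2)) / length(X)
    if (!is.null(reg)) yhat[k] <- nn_forward(reg, xf)$out
  }
  rl <- if (is.null(reg)) NA_real_ else regressor_loss(yz, yhat, loss_type)
  list(recon = recon, rloss = rl)
}

#' Fit a task-guided Wasserstein GAN to a connectome dataset
#'
#' Trains the four-network system — BrainNetCNN encoder, MLP decoder,
#' Wasserstein critic with gradient penalty, and (when `task_alpha > 0`) a
#' task-guided regressor — on `(matrix, score)` pairs. The generator is the
#' encoder-decoder composition: a synthesized matrix is the decoded version
#' of an input's latent code, and the combined objective adds
#' `task_alpha` times the regression loss of the score predicted from the
#' synthesized matrix to the adversarial loss, so the latent space is pushed
#' to encode score-relevant variation. With `task_alpha = 0` the model is a
#' plain WGAN-GP (no regressor, no early stopping).
#'
#' Optimization alternates `critic_steps_per_gen` critic minibatch updates
#' with one generator (+ regressor) update. Scores are standardized
#' internally for the regressor branch (training-set mean and SD; logged
#' regressor losses are on that scale). When a validation set is given in
#' task-guided mode, the validation regressor loss is tracked every epoch;
#' training stops once it has not improved for `patience` epochs after
#' `warmup_epochs`, and the returned model is the one from the best
#' validation epoch. Non-finite losses abort training with a warning and
#' return the last usable model.
#'
#' @param data training `connectome_dataset`.
#' @param validation optional validation `connectome_dataset` (required for
#'   early stopping in task-guided mode).
#' @param spec a [network_spec()]; defaults to `network_spec(n)` for the
#'   data's node count.
#' @param control a [gan_control()].
#' @return object of class `"tg_gan"` with the trained networks, the spec
#'   and control, a per-epoch `log` data frame (critic loss, adversarial
#'   loss, training/validation regressor loss, reconstruction error),
#'   `best_epoch` and `stopped_epoch`.
#' @seealso [reconstruct()], [augment()], [latent_pca()],
#'   [simulate.tg_gan()]
#' @export
tg_gan <- function(data, validation = NULL, spec = NULL,
                   control = gan_control()) {
  stopifnot(inherits(data, "connectome_dataset"))
  n <- n_nodes(data$matrices[[1L]])
  if (is.null(spec)) spec <- network_spec(n)
  if (spec$n_nodes != n)
    stop("spec node count does not match the data", call. = FALSE)
  if (!is.null(validation) &&
      n_nodes(validation$matrices[[1L]]) != n)
    stop("validation node count does not match the data", call. = FALSE)
  task <- control$task_alpha > 0
  X <- lapply(data$matrices, as_weight_matrix)
  y <- data$scores$score
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  yz <- (y - y_mean) / y_sd
  Xv <- if (!is.null(validation)) lapply(validation$matrices,
                                         as_weight_matrix)
  yvz <- if (!is.null(validation)) (validation$scores$score - y_mean) / y_sd

  with_seed(control$seed, {
    enc <- build_encoder(spec)
    dec <- build_decoder(spec)
    critic <- build_critic(spec)
    reg <- if (task) build_regressor(spec)
    st_e <- adam_init(enc); st_d <- adam_init(dec)
    st_c <- adam_init(critic)
    st_r <- if (task) adam_init(reg)

    N <- length(X)
    log_rows <- vector("list", control$max_epochs)
    best <- list(loss = Inf, epoch = 0L,
                 enc = enc, dec = dec, critic = critic, reg = reg)
    diverged <- FALSE
    stopped <- control$max_epochs
    for (epoch in seq_len(control$max_epochs)) {
      idx <- sample.int(N)
      batches <- split(idx, ceiling(seq_along(idx) / control$batch_size))
      closses <- advs <- rlosses <- c()
      for (bi in seq_along(batches)) {
        xb <- X[batches[[bi]]]
        cu <- critic_update(critic, st_c, enc, dec, xb, control, n)
        critic <- cu$critic; st_c <- cu$state
        closses <- c(closses, cu$loss)
        if (task) {
          # the regressor trains supervised on every minibatch (reusing the
          # critic step's synthesized matrices); the minimax schedule only
          # fixes the critic:generator ratio
          ru <- regressor_update(reg, st_r, cu$xf, yz[batches[[bi]]],
                                 control)
          reg <- ru$reg; st_r <- ru$state
        }
        # one generator step per critic_steps_per_gen critic steps; short
        # epochs still get at least one generator step
        if (bi %% control$critic_steps_per_gen == 0L ||
            (bi == length(batches) && is.null(advs))) {
          gu <- generator_update(enc, dec, reg, st_e, st_d, st_r, critic,
                                 xb, yz[batches[[bi]]], control, n)
          enc <- gu$enc; dec <- gu$dec; reg <- gu$reg
          st_e <- gu$st_e; st_d <- gu$st_d; st_r <- gu$st_r
          advs <- c(advs, gu$adv)
          rlosses <- c(rlosses, gu$rloss)
        }
      }
      if (any(!is.finite(c(closses, advs, rlosses)))) {
        warning(sprintf("non-finite loss at epoch %d; stopping early", epoch))
        diverged <- TRUE
        stopped <- epoch
        break
      }
      ev_tr <- eval_pass(enc, dec, reg, X, yz, n, control$regressor_loss_type)
      ev_va <- if (!is.null(Xv))
        eval_pass(enc, dec, reg, Xv, yvz, n, control$regressor_loss_type)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, critic_loss = mean(closses),
        generator_adv_loss = mean(advs),
        regressor_loss_train = ev_tr$rloss,
        regressor_loss_val = if (is.null(Xv)) NA_real_ else ev_va$rloss,
        recon_error_train = ev_tr$recon)
      if (control$verbose > 0 && epoch %% control$verbose == 0)
        message(sprintf(
          "epoch %4d | critic %8.4f | adv %8.4f | reg(tr) %s | reg(val) %s",
          epoch, mean(closses), mean(advs),
          formatC(ev_tr$rloss, digits = 4, format = "f"),
          if (is.null(Xv)) "-" else formatC(ev_va$rloss, digits = 4,
                                            format = "f")))
      if (task && !is.null(Xv)) {
        if (is.finite(ev_va$rloss) && ev_va$rloss < best$loss - 1e-12) {
          best <- list(loss = ev_va$rloss, epoch = epoch, enc = enc,
                       dec = dec, critic = critic, reg = reg)
        }
        if (epoch - max(best$epoch, control$warmup_epochs) >=
            control$patience) {
          stopped <- epoch
          break
        }
      }
      stopped <- epoch
    }
    log <- do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)])
    use_best <- task && !is.null(Xv) && best$epoch > 0L &&
      identical(control$checkpoint, "best")
    structure(list(
      encoder = if (use_best) best$enc else enc,
      decoder = if (use_best) best$dec else dec,
      critic = if (use_best) best$critic else critic,
      regressor = if (!task) NULL else if (use_best) best$reg else reg,
      spec = spec, control = control, log = log,
      best_epoch = if (use_best) best$epoch else stopped,
      stopped_epoch = stopped, diverged = diverged,
      task_guided = task, n_nodes = n,
      score_center = y_mean, score_scale = y_sd,
      node_labels = node_labels(data$matrices[[1L]])),
      class = "tg_gan")
  })
}

#' Reconstruct a connectivity matrix through the trained generator
#'
#' Encodes a matrix to its latent code and decodes it back:
#' `G(D(x))`. The output is symmetric with a zero diagonal by construction
#' and non-negative thanks to the decoder's softplus output layer.
#'
#' @param model a fitted [tg_gan()] model.
#' @param m a `connectivity_matrix` (or plain matrix) with the model's node
#'   count.
#' @return a `connectivity_matrix`.
#' @export
reconstruct <- function(model, m) {
  stopifnot(inherits(model, "tg_gan"))
  w <- as_weight_matrix(as.matrix(m))
  if (nrow(w) != model$n_nodes)
    stop(sprintf("model expects %d nodes, got %d", model$n_nodes, nrow(w)),
         call. = FALSE)
  z <- nn_forward(model$encoder, w)$out
  matricize(nn_forward(model$decoder, z)$out, node_labels = model$node_labels)
}

#' Encode a dataset into the latent space
#'
#' @param model a fitted [tg_gan()] model.
#' @param d a `connectome_dataset`.
#' @return numeric matrix, one row of latent coordinates per subject
#'   (dropout off, deterministic).
#' @export
encode_dataset <- function(model, d) {
  stopifnot(inherits(model, "tg_gan"), inherits(d, "connectome_dataset"))
  Z <- t(vapply(d$matrices, function(m)
    nn_forward(model$encoder, as_weight_matrix(m))$out,
    numeric(model$spec$latent_dim)))
  rownames(Z) <- d$scores$subject_id
  Z
}

#' Grid search over dropout rate and task weight
#'
#' Trains one model per `(dropout_p, task_alpha)` cell and picks the cell
#' minimizing the sum of the training and validation regressor losses at the
#' returned (early-stopped) epoch; ties go to the smaller dropout, then the
#' smaller alpha. The companion WGAN-GP baseline is conventionally given the
#' selected dropout rate.
#'
#' @param data,validation training and validation `connectome_dataset`s.
#' @param spec a [network_spec()] (its `dropout_p` is overridden per cell).
#' @param control a [gan_control()] (its `task_alpha` is overridden per
#'   cell).
#' @param dropout_values,alpha_values numeric grids, values in (0, 1].
#' @param trainer optional override for testing/benchmarking: a
#'   `function(dropout_p, task_alpha)` returning a list with elements
#'   `train_loss` and `val_loss` (and optionally `model`); defaults to
#'   fitting [tg_gan()] per cell.
#' @return list with `dropout_p`, `task_alpha`, the per-cell losses
#'   (`cells`), and the winning `model` (when the default trainer ran).
#' @export
grid_search <- function(data, validation, spec, control,
                        dropout_values = seq(0.1, 0.5, by = 0.1),
                        alpha_values = seq(0.1, 1.0, by = 0.1),
                        trainer = NULL) {
  stopifnot(length(dropout_values) >= 1, length(alpha_values) >= 1,
            all(dropout_values > 0 & dropout_values <= 1),
            all(alpha_values > 0 & alpha_values <= 1))
  if (is.null(trainer))
    trainer <- function(p, a) {
      sp <- spec; sp$dropout_p <- p
      ct <- control; ct$task_alpha <- a
      fit <- tg_gan(data, validation, sp, ct)
      row <- fit$log[fit$log$epoch == fit$best_epoch, ]
      list(train_loss = row$regressor_loss_train,
           val_loss = row$regressor_loss_val, model = fit)
    }
  cells <- expand.grid(dropout_p = sort(dropout_values),
                       task_alpha = sort(alpha_values))
  cells$train_loss <- cells$val_loss <- NA_real_
  models <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    res <- trainer(cells$dropout_p[i], cells$task_alpha[i])
    cells$train_loss[i] <- res$train_loss
    cells$val_loss[i] <- res$val_loss
    models[i] <- list(res$model)
  }
  cells$total <- cells$train_loss + cells$val_loss
  ord <- order(cells$total, cells$dropout_p, cells$task_alpha)
  best <- ord[1L]
  list(dropout_p = cells$dropout_p[best], task_alpha = cells$task_alpha[best],
       cells = cells[, c("dropout_p", "task_alpha", "train_loss",
                         "val_loss", "total")],
       model = models[[best]])
}
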