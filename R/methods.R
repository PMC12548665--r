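#' @export
print.tg_gan <- function(x, ...) {
  cat(sprintf("%s model: %d nodes, latent dim %d\n",
              if (x$task_guided) "Task-guided adversarial (TG GAN II)"
              else "WGAN-GP",
              x$n_nodes, x$spec$latent_dim))
  cat(sprintf("  trained %d epochs (best epoch %d)%s\n", x$stopped_epoch,
              x$best_epoch, if (x$diverged) " [diverged]" else ""))
  if (x$task_guided && nrow(x$log)) {
    row <- x$log[x$log$epoch == x$best_epoch, ]
    cat(sprintf("  regressor loss (standardized score): train %.4f, val %s\n",
                row$regressor_loss_train,
                ifelse(is.na(row$regressor_loss_val), "-",
                       sprintf("%.4f", row$regressor_loss_val))))
  }
  invisible(x)
}

#' Summarize a fitted adversarial model
#'
#' @param object a fitted [tg_gan()] model.
#' @param ... ignored.
#' @return list with the loss trajectory endpoints, reconstruction error,
#'   and early-stopping information.
#' @export
summary.tg_gan <- function(object, ...) {
  lg <- object$log
  out <- list(
    task_guided = object$task_guided,
    n_nodes = object$n_nodes,
    latent_dim = object$spec$latent_dim,
    epochs_run = object$stopped_epoch,
    best_epoch = object$best_epoch,
    diverged = object$diverged,
    critic_loss_final = utils::tail(lg$critic_loss, 1),
    recon_error_first = lg$recon_error_train[1L],
    recon_error_final = utils::tail(lg$recon_error_train, 1),
    regressor_loss_val_best =
      if (object$task_guided) min(c(Inf, lg$regressor_loss_val), na.rm = TRUE)
      else NA_real_)
  class(out) <- "summary.tg_gan"
  out
}

#' @export
print.summary.tg_gan <- function(x, ...) {
  cat(sprintf("%s, %d nodes, latent dim %d\n",
              if (x$task_guided) "Task-guided adversarial model (TG GAN II)"
              else "WGAN-GP baseline", x$n_nodes, x$latent_dim))
  cat(sprintf("  epochs: %d (best %d)%s\n", x$epochs_run, x$best_epoch,
              if (x$diverged) " [diverged]" else ""))
  cat(sprintf("  reconstruction error: %.4f -> %.4f\n",
              x$recon_error_first, x$recon_error_final))
  if (x$task_guided)
    cat(sprintf("  best validation regressor loss: %.4f\n",
                x$regressor_loss_val_best))
  invisible(x)
}

#' Plot training trajectories of a fitted model
#'
#' Base-graphics loss curves: critic loss, reconstruction error, and (when
#' task-guided) training/validation regressor losses.
#'
#' @param x a fitted [tg_gan()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tg_gan <- function(x, ...) {
  lg <- x$log
  op <- graphics::par(mfrow = c(1, if (x$task_guided) 3L else 2L),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(lg$epoch, lg$critic_loss, type = "l", xlab = "epoch",
                 ylab = "critic loss", main = "critic", ...)
  graphics::plot(lg$epoch, lg$recon_error_train, type = "l", xlab = "epoch",
                 ylab = "mean Frobenius error", main = "reconstruction", ...)
  if (x$task_guided) {
    graphics::matplot(lg$epoch,
                      cbind(lg$regressor_loss_train, lg$regressor_loss_val),
                      type = "l", lty = 1, col = c("black", "red"),
                      xlab = "epoch", ylab = "regressor loss (std. score)",
                      main = "task branch", ...)
    graphics::abline(v = x$best_epoch, lty = 3)
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("black", "red"), bty = "n")
  }
  invisible(x)
}

#' Predictions from a fitted adversarial model
#'
#' `type = "latent"` returns the encoder's latent coordinates;
#' `type = "reconstruction"` the decoded matrices `G(D(x))`;
#' `type = "score"` the task-guided regressor's score predictions for the
#' synthesized matrices, mapped back to the original score scale (only for
#' task-guided models).
#'
#' @param object a fitted [tg_gan()] model.
#' @param newdata a `connectome_dataset`.
#' @param type what to predict.
#' @param ... ignored.
#' @export
predict.tg_gan <- function(object, newdata,
                           type = c("latent", "reconstruction", "score"),
                           ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "connectome_dataset"))
  switch(type,
    latent = encode_dataset(object, newdata),
    reconstruction = lapply(newdata$matrices,
                            function(m) reconstruct(object, m)),
    score = {
      if (!object$task_guided)
        stop("score prediction needs a task-guided model", call. = FALSE)
      vapply(newdata$matrices, function(m) {
        xf <- as_weight_matrix(as.matrix(reconstruct(object, m)))
        nn_forward(object$regressor, xf)$out * object$score_scale +
          object$score_center
      }, 1)
    })
}

#' Reconstruction residuals of a fitted model
#'
#' Edge-vector residuals `x - G(D(x))` per subject: how much of each
#' connection the generator fails to reproduce.
#'
#' @param object a fitted [tg_gan()] model.
#' @param data a `connectome_dataset`.
#' @param ... ignored.
#' @return matrix (subjects x edges) of residuals in the package edge
#'   ordering.
#' @export
residuals.tg_gan <- function(object, data, ...) {
  stopifnot(inherits(data, "connectome_dataset"))
  t(vapply(data$matrices, function(m) {
    r <- as_weight_matrix(as.matrix(m)) -
      as_weight_matrix(as.matrix(reconstruct(object, m)))
    as.numeric(t(r)[upper.tri(r)])
  }, numeric(object$n_nodes * (object$n_nodes - 1) / 2)))
}
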