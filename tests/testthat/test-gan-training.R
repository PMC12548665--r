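test_that("training is reproducible and task_alpha = 0 omits the regressor", {
  gen <- generate_connectomes(synth_config(n_subjects = 8, n_nodes = 8,
                                           n_signal_edges = 4, seed = 31))
  spec <- tiny_spec(8)
  ctl <- gan_control(max_epochs = 3, warmup_epochs = 100, seed = 77,
                     task_alpha = 0.4)
  fit1 <- tg_gan(gen$data, NULL, spec, ctl)
  fit2 <- tg_gan(gen$data, NULL, spec, ctl)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$encoder$layers, fit2$encoder$layers)
  expect_s3_class(fit1$regressor, "brainnet_network")

  ctl0 <- ctl; ctl0$task_alpha <- 0
  fit0 <- tg_gan(gen$data, NULL, spec, ctl0)
  expect_null(fit0$regressor)
  expect_false(fit0$task_guided)
  expect_true(all(is.na(fit0$log$regressor_loss_train)))
})

test_that("reconstruction error drops by at least 20% over a 100-epoch run", {
  gen <- generate_connectomes(synth_config(n_subjects = 40, n_nodes = 30,
                                           seed = 19))
  spec <- network_spec(30, latent_dim = 16, e2e_channels = c(4, 8),
                       e2n_channels = 16, n2g_units = 32, dropout_p = 0.1)
  fit <- tg_gan(gen$data, NULL, spec,
                gan_control(max_epochs = 100, warmup_epochs = 1000,
                            seed = 23, task_alpha = 0.5))
  r <- fit$log$recon_error_train
  expect_lt(tail(r, 1), 0.8 * r[1])
  expect_true(all(is.finite(fit$log$critic_loss)))
})

test_that("reconstructions satisfy the connectivity contract and are deterministic", {
  fx <- fixture_model()
  local_seed_eval(32, {
    for (rep in 1:5) {
      m <- random_cm(10)
      r <- reconstruct(fx$model, m)
      w <- as.matrix(r)
      expect_true(all(diag(w) == 0))
      expect_true(all(w >= 0))
      expect_equal(w, t(w))
    }
  })
  m <- fx$data$matrices[[1]]
  expect_identical(as.matrix(reconstruct(fx$model, m)),
                   as.matrix(reconstruct(fx$model, m)))
  expect_error(reconstruct(fx$model, random_cm(9, seed = 1)), "nodes")
})

test_that("early stopping fires by the warmup-plus-patience rule", {
  gen <- generate_connectomes(synth_config(n_subjects = 10, n_nodes = 8,
                                           n_signal_edges = 4, seed = 33))
  d <- gen$data
  tr <- d[1:7]; va <- d[8:10]
  ctl <- gan_control(max_epochs = 60, warmup_epochs = 5, patience = 4,
                     seed = 9, task_alpha = 0.5, checkpoint = "best")
  fit <- tg_gan(tr, va, tiny_spec(8), ctl)
  s <- fit$stopped_epoch
  if (s < ctl$max_epochs) {
    # the rule: stopped exactly when patience epochs passed since the later
    # of the best epoch and the warmup boundary
    expect_identical(s - max(fit$best_epoch, ctl$warmup_epochs),
                     ctl$patience)
    expect_gte(s, ctl$warmup_epochs + ctl$patience)
  }
  # under checkpoint = "best" the returned model is the best-validation one
  vl <- fit$log$regressor_loss_val
  expect_identical(fit$best_epoch, which.min(vl))
  # under the default checkpoint = "final" the stopping rule is identical
  # but the final-state parameters are kept
  ctl_f <- ctl; ctl_f$checkpoint <- "final"
  fit_f <- tg_gan(tr, va, tiny_spec(8), ctl_f)
  expect_identical(fit_f$stopped_epoch, s)
  expect_identical(fit_f$log, fit$log)
  expect_identical(fit_f$best_epoch, fit_f$stopped_epoch)
})

test_that("grid search selects the cell with minimal train+validation loss", {
  # injected losses with a unique minimum
  fake <- function(p, a) list(train_loss = abs(p - 0.3) + abs(a - 0.6),
                              val_loss = 0)
  gs <- grid_search(NULL, NULL, NULL, NULL,
                    dropout_values = c(0.1, 0.3, 0.5),
                    alpha_values = c(0.2, 0.6, 1.0), trainer = fake)
  expect_equal(gs$dropout_p, 0.3)
  expect_equal(gs$task_alpha, 0.6)
  expect_identical(nrow(gs$cells), 9L)
  # single-cell grid returns that cell; ties break to smaller dropout/alpha
  gs1 <- grid_search(NULL, NULL, NULL, NULL, 0.2, 0.7,
                     trainer = function(p, a) list(train_loss = 1,
                                                   val_loss = 1))
  expect_equal(gs1$dropout_p, 0.2)
  expect_equal(gs1$task_alpha, 0.7)
  gs2 <- grid_search(NULL, NULL, NULL, NULL, c(0.1, 0.2), c(0.3, 0.4),
                     trainer = function(p, a) list(train_loss = 0,
                                                   val_loss = 0))
  expect_equal(gs2$dropout_p, 0.1)
  expect_equal(gs2$task_alpha, 0.3)
  # the benchmarked grid geometry: 5 dropout x 10 alpha = 50 cells
  gs_shape <- expand.grid(dropout_p = seq(0.1, 0.5, by = 0.1),
                          task_alpha = seq(0.1, 1.0, by = 0.1))
  expect_identical(nrow(gs_shape), 50L)
})

test_that("checkpoints round-trip through JSON", {
  fx <- fixture_model()
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_tg_gan(fx$model, path)
  m2 <- load_tg_gan(path)
  x <- as.matrix(fx$data$matrices[[2]])
  expect_equal(as.matrix(reconstruct(m2, x)),
               as.matrix(reconstruct(fx$model, x)), tolerance = 1e-12)
  expect_equal(m2$log$critic_loss, fx$model$log$critic_loss)
  expect_identical(m2$task_guided, fx$model$task_guided)
})

test_that("model methods expose latents, residuals and score predictions", {
  fx <- fixture_model()
  d <- fx$data
  Z <- predict(fx$model, d, type = "latent")
  expect_identical(dim(Z), c(16L, 6L))
  res <- residuals(fx$model, d)
  expect_identical(dim(res), c(16L, 45L))
  sc <- predict(fx$model, d, type = "score")
  expect_length(sc, 16)
  expect_true(all(is.finite(sc)))
  expect_output(print(fx$model), "Task-guided")
  s <- summary(fx$model)
  expect_s3_class(s, "summary.tg_gan")
})
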