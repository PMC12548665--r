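# Shared fixtures. Heavier objects (a small trained model) are built once
# per test run and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("tggan-test-")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}

random_cm <- function(n, seed = NULL) {
  build <- function() {
    w <- matrix(abs(stats::rnorm(n * n)), n)
    w <- w + t(w)
    diag(w) <- 0
    connectivity_matrix(w)
  }
  if (is.null(seed)) build() else local_seed_eval(seed, build())
}

local_seed_eval <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  force(expr)
}

# tiny dataset for structural tests: N subjects, n nodes
tiny_dataset <- function(N = 12, n = 10, seed = 99, score_sd = 10) {
  local_seed_eval(seed, {
    mats <- lapply(seq_len(N), function(i) {
      w <- matrix(abs(stats::rnorm(n * n)), n)
      w <- w + t(w)
      diag(w) <- 0
      connectivity_matrix(w)
    })
    connectome_dataset(mats,
                       data.frame(subject_id = sprintf("s%02d", seq_len(N)),
                                  score = stats::rnorm(N, 100, score_sd)))
  })
}

tiny_spec <- function(n) {
  E <- n * (n - 1) / 2
  network_spec(n, latent_dim = 6, e2e_channels = c(2, 3), e2n_channels = 4,
               n2g_units = 8, fc_widths_encoder = c(12, 6),
               fc_widths_decoder = c(12, 16, 24, 32, E),
               fc_widths_regressor = c(12, 8, 4, 1), dropout_p = 0.1)
}

# a briefly trained task-guided model on a tiny synthetic dataset; cached
fixture_model <- function() {
  if (!is.null(.fixture_env$model)) return(.fixture_env$model)
  gen <- generate_connectomes(synth_config(n_subjects = 16, n_nodes = 10,
                                           n_signal_edges = 8, seed = 5))
  d <- gen$data
  fit <- tg_gan(d, NULL, tiny_spec(10),
                gan_control(max_epochs = 20, warmup_epochs = 1000,
                            seed = 4, task_alpha = 0.5))
  .fixture_env$model <- list(model = fit, data = d, gt = gen$ground_truth)
  .fixture_env$model
}
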