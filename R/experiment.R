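# ---- model checkpoints (plain JSON, text-only) -----------------------------

net_to_list <- function(net) {
  list(role = net$role, n_nodes = net$n_nodes,
       layers = lapply(net$layers, function(l) {
         out <- l[setdiff(names(l), param_names)]
         for (k in intersect(param_names, names(l)))
           out[[k]] <- list(dim = dim(l[[k]]) %||% length(l[[k]]),
                            data = as.numeric(l[[k]]))
         out
       }))
}

net_from_list <- function(x) {
  layers <- lapply(x$layers, function(l) {
    for (k in intersect(param_names, names(l))) {
      p <- l[[k]]
      v <- as.numeric(p$data)
      if (length(p$dim) > 1L) dim(v) <- as.integer(p$dim)
      l[[k]] <- v
    }
    l
  })
  new_network(layers, as.integer(x$n_nodes), x$role)
}

#' Save / load a fitted model as a JSON checkpoint
#'
#' Serializes the four networks, the architecture spec, the training
#' control, the training log and the score scaling into a single
#' plain-text JSON file, and restores a functionally identical model.
#'
#' @param model a fitted [tg_gan()] model.
#' @param path checkpoint file path (`.json`).
#' @export
save_tg_gan <- function(model, path) {
  stopifnot(inherits(model, "tg_gan"))
  obj <- list(format = "tggan-checkpoint", version = "1",
              encoder = net_to_list(model$encoder),
              decoder = net_to_list(model$decoder),
              critic = net_to_list(model$critic),
              regressor = if (!is.null(model$regressor))
                net_to_list(model$regressor),
              spec = unclass(model$spec), control = unclass(model$control),
              log = model$log, best_epoch = model$best_epoch,
              stopped_epoch = model$stopped_epoch,
              diverged = model$diverged, task_guided = model$task_guided,
              n_nodes = model$n_nodes, score_center = model$score_center,
              score_scale = model$score_scale,
              node_labels = model$node_labels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_tg_gan
#' @export
load_tg_gan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                           simplifyDataFrame = FALSE)
  if (!identical(x$format, "tggan-checkpoint"))
    stop("not a tggan checkpoint: ", path, call. = FALSE)
  spec <- x$spec
  for (k in names(spec)) spec[[k]] <- unlist(spec[[k]])
  class(spec) <- "network_spec"
  control <- x$control
  for (k in names(control)) control[[k]] <- unlist(control[[k]])
  class(control) <- "gan_control"
  log <- as.data.frame(lapply(
    as.data.frame(do.call(rbind, x$log)),
    function(col) as.numeric(unlist(lapply(col, function(v)
      if (is.null(v)) NA_real_ else v)))))
  structure(list(encoder = net_from_list(x$encoder),
                 decoder = net_from_list(x$decoder),
                 critic = net_from_list(x$critic),
                 regressor = if (!is.null(x$regressor))
                   net_from_list(x$regressor),
                 spec = spec, control = control, log = log,
                 best_epoch = as.integer(x$best_epoch),
                 stopped_epoch = as.integer(x$stopped_epoch),
                 diverged = isTRUE(x$diverged),
                 task_guided = isTRUE(x$task_guided),
                 n_nodes = as.integer(x$n_nodes),
                 score_center = as.numeric(x$score_center),
                 score_scale = as.numeric(x$score_scale),
                 node_labels = as.character(unlist(x$node_labels))),
            class = "tg_gan")
}

# ---- experiment configuration ----------------------------------------------

# deterministic substream seed below 2^31, derived from a root seed and a
# stage name
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629) + 1L
}

#' Default end-to-end experiment configuration
#'
#' Assembles the configuration consumed by [run_experiment()]: synthetic
#' data settings (or a directory of real data), the rank-interleaved split
#' rule, network and training settings, optional grid search, augmentation
#' levels, fidelity densities and the CV benchmark. The defaults describe a
#' desk-scale run: 30-node synthetic connectomes, 113 subjects (so the
#' stride-3 rank split retains 75 discovery subjects), small network
#' widths, and short training.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @param synth list of [synth_config()] overrides (ignored when
#'   `data_dir` is given).
#' @param data_dir optional directory of a saved dataset ([read_dataset()]).
#' @param holdout_stride,holdout_offset split rule for discovery/test and
#'   train/validation splits.
#' @param spec list of [network_spec()] overrides.
#' @param control list of [gan_control()] overrides.
#' @param grid `NULL` to skip grid search, or a list with `dropout_values`
#'   and `alpha_values`.
#' @param augmentation_factors per-pair synthesis counts `k` to benchmark.
#' @param densities fidelity edge densities.
#' @param cv list of [cv_config()] overrides.
#' @param cv_models which generative models' augmentations to benchmark
#'   (subset of `"tggan"`, `"wgangp"`).
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(seed = 1L,
                              synth = list(n_subjects = 113L, n_nodes = 30L),
                              data_dir = NULL,
                              holdout_stride = 3L, holdout_offset = 1L,
                              spec = list(latent_dim = 16L,
                                          e2e_channels = c(4L, 8L),
                                          e2n_channels = 16L,
                                          n2g_units = 32L),
                              control = list(max_epochs = 150L,
                                             warmup_epochs = 120L,
                                             patience = 30L,
                                             task_alpha = 1.0),
                              grid = NULL,
                              augmentation_factors = 1L,
                              densities = seq(0.05, 0.25, by = 0.05),
                              cv = list(),
                              cv_models = "tggan") {
  structure(list(seed = as.integer(seed), synth = synth, data_dir = data_dir,
                 holdout_stride = as.integer(holdout_stride),
                 holdout_offset = as.integer(holdout_offset),
                 spec = spec, control = control, grid = grid,
                 augmentation_factors = as.integer(augmentation_factors),
                 densities = densities, cv = cv,
                 cv_models = match.arg(cv_models, c("tggan", "wgangp"),
                                       several.ok = TRUE)),
            class = "experiment_config")
}

write_json_out <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

#' Run the full augmentation-and-prediction experiment
#'
#' End-to-end orchestration: data acquisition (synthetic generation or
#' loading), rank-interleaved discovery/test and train/validation splits,
#' optional grid search, task-guided and plain WGAN-GP training,
#' reconstruction fidelity report, latent-space PCA, augmentation at each
#' requested level, the repeated nested CV benchmark on the baseline and
#' each augmented dataset, Welch comparisons against the baseline
#' (Bonferroni-corrected over the augmentation levels), and feature-weight
#' reliability. Every artifact is written under `out_dir` together with the
#' config snapshot and a hash manifest; a rerun with the same config
#' reproduces the same results.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @return (invisibly) a list with the in-memory results.
#' @export
run_experiment <- function(config = experiment_config(), out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) message(sprintf("[%s] %s", format(Sys.time(),
                                                            "%H:%M:%S"), name))
  cfg_path <- file.path(out_dir, "config.json")
  write_json_out(unclass(config), cfg_path)

  stage("data")
  if (is.null(config$data_dir)) {
    sc <- do.call(synth_config,
                  utils::modifyList(config$synth,
                                    list(seed = derive_seed(config$seed,
                                                            "synth"))))
    gen <- generate_connectomes(sc)
    data_all <- gen$data
    write_json_out(list(signal_edges = gen$ground_truth$signal_edges,
                        slopes = gen$ground_truth$slopes),
                   file.path(out_dir, "ground_truth.json"))
  } else {
    data_all <- read_dataset(config$data_dir)
  }

  stage("split")
  split <- rank_interleaved_split(data_all, config$holdout_stride,
                                  config$holdout_offset)
  discovery <- data_all[split$discovery_idx]
  test <- data_all[split$test_idx]
  inner <- rank_interleaved_split(discovery, config$holdout_stride,
                                  config$holdout_offset)
  d_train <- discovery[inner$discovery_idx]
  d_val <- discovery[inner$test_idx]
  write_json_out(list(discovery = split$discovery_ids,
                      test = split$test_ids,
                      gan_train = inner$discovery_ids,
                      gan_validation = inner$test_ids),
                 file.path(out_dir, "split.json"))

  n <- n_nodes(data_all$matrices[[1L]])
  spec <- do.call(network_spec, c(list(n_nodes = n), config$spec))
  control <- do.call(gan_control,
                     utils::modifyList(config$control,
                                       list(seed = derive_seed(config$seed,
                                                               "train"))))

  if (!is.null(config$grid)) {
    stage("grid search")
    gs <- grid_search(d_train, d_val, spec, control,
                      config$grid$dropout_values, config$grid$alpha_values)
    spec$dropout_p <- gs$dropout_p
    control$task_alpha <- gs$task_alpha
    utils::write.csv(gs$cells, file.path(out_dir, "grid_search.csv"),
                     row.names = FALSE)
  }

  stage("train task-guided model")
  fit_tg <- tg_gan(d_train, d_val, spec, control)
  utils::write.csv(fit_tg$log, file.path(out_dir, "loss_tggan.csv"),
                   row.names = FALSE)
  stage("train WGAN-GP baseline")
  control_w <- control
  control_w$task_alpha <- 0
  fit_w <- tg_gan(d_train, d_val, spec, control_w)
  utils::write.csv(fit_w$log, file.path(out_dir, "loss_wgangp.csv"),
                   row.names = FALSE)
  models <- list(tggan = fit_tg, wgangp = fit_w)

  stage("fidelity")
  fids <- lapply(models, function(m) {
    recon <- connectome_dataset(
      lapply(discovery$matrices, function(x) reconstruct(m, x)),
      discovery$scores, atlas_name = discovery$atlas_name)
    fidelity_report(discovery, recon, config$densities)
  })
  write_fidelity_report(fids$tggan, file.path(out_dir, "fidelity_tggan.json"))
  write_fidelity_report(fids$wgangp,
                        file.path(out_dir, "fidelity_wgangp.json"))

  stage("latent space")
  latent <- lapply(models, function(m)
    list(train = latent_pca(m, d_train)[c("r", "p")],
         validation = latent_pca(m, d_val)[c("r", "p")]))
  write_json_out(latent, file.path(out_dir, "latent_pca.json"))

  stage("prediction benchmark")
  cvc <- do.call(cv_config,
                 utils::modifyList(config$cv,
                                   list(seed = derive_seed(config$seed,
                                                           "cv"))))
  runs <- list(baseline = discovery)
  for (mn in config$cv_models)
    for (k in config$augmentation_factors)
      runs[[sprintf("%s_plus%d00", mn, k)]] <-
        augment(discovery, models[[mn]], k = k)
  cv_results <- lapply(runs, repeated_nested_cv, cfg = cvc)
  evals <- lapply(cv_results, evaluate_test, test_data = test)
  summary_tab <- do.call(rbind, lapply(names(evals), function(nm) {
    s <- attr(evals[[nm]], "summary")
    data.frame(setting = nm, training_size = length(runs[[nm]]$matrices),
               test_r_mean = s[["r_mean"]], test_r_sd = s[["r_sd"]],
               test_rmse_mean = s[["rmse_mean"]],
               test_rmse_sd = s[["rmse_sd"]])
  }))
  utils::write.csv(summary_tab, file.path(out_dir, "prediction_summary.csv"),
                   row.names = FALSE)

  stage("comparisons")
  lvl <- setdiff(names(evals), "baseline")
  comparisons <- lapply(lvl, function(nm)
    compare_accuracy(evals[[nm]]$test_r, evals$baseline$test_r,
                     n_comparisons = length(lvl)))
  names(comparisons) <- lvl
  write_json_out(comparisons, file.path(out_dir, "comparisons.json"))

  rel <- lapply(cv_results, weight_reliability)
  for (nm in names(rel))
    utils::write.csv(rel[[nm]],
                     file.path(out_dir, sprintf("weights_%s.csv", nm)),
                     row.names = FALSE)

  stage("manifest")
  manifest <- write_manifest(out_dir, cfg_path, config$seed)
  invisible(list(split = split, models = models, fidelity = fids,
                 latent = latent, cv = cv_results, evaluations = evals,
                 summary = summary_tab, comparisons = comparisons,
                 reliability = rel, manifest = manifest))
}

#' Provenance manifest for an output directory
#'
#' `write_manifest()` stamps an output directory with the package version,
#' the MD5 of the config snapshot, the seed and the MD5 of every artifact;
#' `validate_manifest()` recomputes the hashes and reports any file that
#' has been altered since the run.
#'
#' @param out_dir results directory.
#' @param config_path path of the config snapshot inside `out_dir`.
#' @param seed the experiment seed.
#' @export
write_manifest <- function(out_dir, config_path, seed) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  hashes <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(package = "tggan",
                   version = as.character(utils::packageVersion("tggan")),
                   seed = seed,
                   config_hash = unname(tools::md5sum(config_path)),
                   files = stats::setNames(as.list(unname(hashes)), files))
  write_json_out(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

#' @rdname write_manifest
#' @return `validate_manifest()`: list with `ok` and a character vector of
#'   mismatching files.
#' @export
validate_manifest <- function(out_dir) {
  mp <- file.path(out_dir, "manifest.json")
  if (!file.exists(mp)) stop("no manifest.json in ", out_dir, call. = FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  bad <- character(0)
  for (f in names(man$files)) {
    p <- file.path(out_dir, f)
    h <- if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
    if (!identical(h, man$files[[f]])) bad <- c(bad, f)
  }
  list(ok = length(bad) == 0L, mismatches = bad)
}
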