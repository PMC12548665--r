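adj_to_cm <- function(adj) connectivity_matrix(adj)

test_that("density binarization keeps exactly the strongest edges with deterministic ties", {
  # fully positive matrix at density 1 -> complete graph
  m <- random_cm(5, seed = 41)
  b <- binarize_by_density(m, 1)
  expect_equal(sum(as.matrix(b)), 5 * 4)
  # n = 4 (E = 6), density 0.5 -> exactly the 3 largest edges survive
  w <- matrix(0, 4, 4)
  vals <- c(10, 2, 8, 5, 1, 9)  # row-major lower triangle
  k <- 0
  for (i in 2:4) for (j in 1:(i - 1)) {
    k <- k + 1
    w[i, j] <- w[j, i] <- vals[k]
  }
  b <- binarize_by_density(connectivity_matrix(w), 0.5)
  vb <- as.numeric(vectorize_lower_triangle(b))
  expect_equal(vb, as.numeric(vals >= 8))
  expect_equal(sum(vb), 3)
  # rank-based: invariant to uniform rescaling
  b2 <- binarize_by_density(connectivity_matrix(w * 37), 0.5)
  expect_equal(as.matrix(b2), as.matrix(b))
  # tie at the cut resolved by (row, column) order, reproducibly
  wt <- matrix(0, 4, 4)
  wt[lower.tri(wt)] <- 1
  wt <- wt + t(wt)
  bt <- binarize_by_density(connectivity_matrix(wt), 0.5)
  expect_equal(as.numeric(vectorize_lower_triangle(bt)),
               c(1, 1, 1, 0, 0, 0))
  expect_error(binarize_by_density(m, 0), "density")
  expect_error(binarize_by_density(m, 1.2), "density")
})

test_that("graph metrics take their closed-form values on canonical graphs", {
  # complete graph K5
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  gm <- graph_metrics(adj_to_cm(k5))
  expect_equal(gm$clustering, rep(1, 5))
  expect_equal(gm$betweenness, rep(0, 5))
  expect_equal(gm$global_efficiency, 1)
  expect_equal(gm$degree, rep(4, 5))
  # star with 4 leaves: center betweenness = C(4,2) = 6 unnormalized
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  gms <- graph_metrics(adj_to_cm(star), normalize = FALSE)
  expect_equal(gms$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(gms$clustering, rep(0, 5))
  gmsn <- graph_metrics(adj_to_cm(star), normalize = TRUE)
  expect_equal(gmsn$betweenness[1], 1)  # 6 * 2 / (4 * 3)
  # two disjoint triangles: the two-block partition has Q = 1/2
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  two <- rbind(cbind(k3, matrix(0, 3, 3)), cbind(matrix(0, 3, 3), k3))
  gm2 <- graph_metrics(adj_to_cm(two))
  expect_equal(gm2$modularity,
               oracle_modularity_value(two, rep(1:2, each = 3)))
  expect_gt(gm2$modularity, 0)
  expect_error(graph_metrics(random_cm(5, seed = 1)), "binary")
})

test_that("metrics match brute-force oracles on random small graphs", {
  local_seed_eval(42, {
    for (rep in 1:20) {
      n <- sample(5:12, 1)
      adj <- random_binary_adj(n, p = runif(1, 0.25, 0.7))
      if (sum(adj) == 0) adj[2, 1] <- adj[1, 2] <- 1
      gm <- graph_metrics(adj_to_cm(adj), normalize = FALSE)
      expect_equal(gm$degree, rowSums(adj), tolerance = 1e-9)
      expect_equal(gm$betweenness, oracle_betweenness(adj),
                   tolerance = 1e-9)
      expect_equal(gm$clustering, oracle_clustering(adj), tolerance = 1e-9)
      expect_equal(gm$global_efficiency, oracle_global_efficiency(adj),
                   tolerance = 1e-9)
      expect_equal(gm$local_efficiency, oracle_local_efficiency(adj),
                   tolerance = 1e-9)
      # modularity: recompute Q from the detected partition by definition
      ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      memb <- igraph::membership(igraph::cluster_fast_greedy(ig))
      expect_equal(gm$modularity,
                   oracle_modularity_value(adj, as.integer(memb)),
                   tolerance = 1e-9)
    }
  })
})

test_that("KL estimator is calibrated against the Gaussian closed form", {
  expect_equal(metric_kl(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)), 0)
  local_seed_eval(43, {
    x <- rnorm(10000, 0, 1)
    y <- rnorm(10000, 1, 1)
    est <- metric_kl(x, y)
    expect_lt(abs(est - 0.5), 0.1)  # closed form: (mu1-mu2)^2 / 2 = 0.5
    # non-negativity across random pairs
    for (rep in 1:100) {
      a <- rnorm(30, runif(1, -1, 1), runif(1, 0.5, 2))
      b <- rnorm(30, runif(1, -1, 1), runif(1, 0.5, 2))
      expect_gte(metric_kl(a, b), 0)
    }
    # convergence: the error shrinks with sample size
    e_small <- abs(metric_kl(rnorm(200), rnorm(200, 1)) - 0.5)
    e_large <- abs(metric_kl(rnorm(20000), rnorm(20000, 1)) - 0.5)
    expect_lt(e_large, e_small)
  })
  expect_error(metric_kl(1:3, 1:10), "at least 5")
  # zero-variance fallback does not error
  expect_true(is.finite(metric_kl(rep(1, 10), rnorm(10))))
})

test_that("Cohen's d follows the paired and pooled definitions", {
  # diffs (1,1,1,3): mean 1.5, sd 1 -> d = 1.5
  x <- c(0, 0, 0, 0); y <- c(1, 1, 1, 3)
  expect_equal(cohens_d(x, y, paired = TRUE), 1.5)
  expect_equal(cohens_d(y, x, paired = TRUE), -1.5)  # antisymmetry
  expect_equal(cohens_d(x, x, paired = TRUE), 0)
  local_seed_eval(44, {
    a <- rnorm(20); b <- rnorm(20, 0.5)
    expect_equal(cohens_d(a, b, paired = FALSE),
                 -cohens_d(b, a, paired = FALSE))
    # pooled definition recomputed by hand
    sp <- sqrt((19 * var(a) + 19 * var(b)) / 38)
    expect_equal(cohens_d(a, b, paired = FALSE), (mean(b) - mean(a)) / sp)
  })
  expect_error(cohens_d(1:3, 1:4, paired = TRUE), "equal length")
})

test_that("mean difference matrix equals the brute-force per-edge mean", {
  d1 <- tiny_dataset(N = 5, n = 6, seed = 45)
  expect_equal(mean_difference_matrix(d1, d1), matrix(0, 6, 6))
  # constant offset on every edge
  off <- lapply(d1$matrices, function(m) {
    w <- as.matrix(m) + 0.25
    diag(w) <- 0
    connectivity_matrix(w)
  })
  d2 <- connectome_dataset(off, d1$scores)
  md <- mean_difference_matrix(d2, d1)
  expect_equal(md[lower.tri(md)], rep(0.25, 15))
  # brute force over random pairs of datasets
  d3 <- tiny_dataset(N = 5, n = 6, seed = 46)
  md2 <- mean_difference_matrix(d1, d3)
  brute <- Reduce(`+`, Map(function(a, b) as.matrix(a) - as.matrix(b),
                           d1$matrices, d3$matrices)) / 5
  expect_equal(md2, brute, ignore_attr = TRUE)
  expect_equal(md2, t(md2))
})

test_that("fidelity report covers the full density-by-metric grid and round-trips", {
  d <- tiny_dataset(N = 6, n = 12, seed = 47)
  rep1 <- fidelity_report(d, d, densities = c(0.1, 0.2, 0.3))
  expect_identical(nrow(rep1$kl), 3L)
  expect_identical(names(rep1$kl), c("density", "strength", "betweenness",
                                     "clustering"))
  expect_identical(nrow(rep1$cohens_d), 3L)
  expect_identical(ncol(rep1$cohens_d), 6L)  # density + 5 measures
  # identical datasets: all zero divergence and zero effect size
  expect_true(all(abs(as.matrix(rep1$kl[, -1])) < 1e-12))
  expect_true(all(abs(as.matrix(rep1$cohens_d[, -1])) < 1e-12))
  expect_true(all(rep1$mean_difference_matrix == 0))
  # default grid matches the benchmark layout: 5 densities
  rep_def <- fidelity_report(d, d)
  expect_equal(rep_def$kl$density, seq(0.05, 0.25, by = 0.05))
  # serialization round-trip
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_fidelity_report(rep_def, path)
  rep2 <- read_fidelity_report(path)
  expect_equal(rep2$kl, rep_def$kl, tolerance = 1e-12)
  expect_equal(rep2$cohens_d, rep_def$cohens_d, tolerance = 1e-12)
  expect_equal(rep2$mean_difference_matrix, rep_def$mean_difference_matrix,
               tolerance = 1e-12)
})
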