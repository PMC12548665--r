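test_that("connectivity matrix validation rejects malformed input", {
  w <- matrix(0, 4, 4)
  w[2, 1] <- w[1, 2] <- 1

  bad <- w; bad[3, 1] <- -0.5; bad[1, 3] <- -0.5
  expect_error(connectivity_matrix(bad), "negative weight.*\\(3, 1\\)")

  bad <- w; bad[2, 1] <- 2  # asymmetric beyond tolerance
  expect_error(connectivity_matrix(bad), "asymmetric")

  bad <- w; bad[2, 2] <- 0.1
  expect_error(connectivity_matrix(bad), "nonzero diagonal")

  bad <- w; bad[3, 4] <- bad[4, 3] <- NaN
  expect_error(connectivity_matrix(bad), "non-finite")

  expect_error(connectivity_matrix(matrix(0, 2, 2)), "at least 3 nodes")
  expect_error(connectivity_matrix(matrix(0, 3, 4)), "not square")

  # sub-tolerance noise is absorbed, not rejected
  w2 <- w; w2[2, 1] <- w2[1, 2] + 1e-10; diag(w2) <- 1e-10
  m <- connectivity_matrix(w2)
  expect_identical(unclass(m)[2, 1], unclass(m)[1, 2])
  expect_true(all(diag(m) == 0))
})

test_that("lower-triangle vectorization uses row-major order and excludes the diagonal", {
  w <- matrix(0, 3, 3)
  w[2, 1] <- w[1, 2] <- 5  # a = w(2,1)
  w[3, 1] <- w[1, 3] <- 7  # b = w(3,1)
  w[3, 2] <- w[2, 3] <- 9  # c = w(3,2)
  expect_equal(as.numeric(vectorize_lower_triangle(connectivity_matrix(w))),
               c(5, 7, 9))
  # n = 4: row-major is (2,1),(3,1),(3,2),(4,1),(4,2),(4,3)
  w4 <- matrix(0, 4, 4)
  k <- 0
  for (i in 2:4) for (j in 1:(i - 1)) {
    k <- k + 1
    w4[i, j] <- w4[j, i] <- k * 10
  }
  expect_equal(as.numeric(vectorize_lower_triangle(connectivity_matrix(w4))),
               (1:6) * 10)
  v0 <- vectorize_lower_triangle(connectivity_matrix(matrix(0, 4, 4)))
  expect_equal(as.numeric(v0), rep(0, 6))
})

test_that("vectorize and matricize are mutual inverses (100 random cases)", {
  local_seed_eval(1, {
    for (rep in 1:50) {
      n <- sample(3:12, 1)
      m <- random_cm(n)
      v <- vectorize_lower_triangle(m)
      expect_equal(as.matrix(matricize(v)), as.matrix(m), tolerance = 1e-14)
    }
    for (rep in 1:50) {
      n <- sample(3:12, 1)
      v <- abs(rnorm(n * (n - 1) / 2))
      expect_equal(as.numeric(vectorize_lower_triangle(matricize(v))),
                   v, tolerance = 1e-14)
    }
  })
})

test_that("matricize rejects non-triangular lengths", {
  expect_error(matricize(rnorm(5)), "triangular")
  expect_error(matricize(rnorm(8)), "triangular")
})

test_that("node reordering permutes weights and labels consistently", {
  m <- random_cm(6, seed = 2)
  expect_equal(as.matrix(reorder_nodes(m, 1:6)), as.matrix(m))
  perm <- c(2, 1, 3, 4, 5, 6)
  twice <- reorder_nodes(reorder_nodes(m, perm), perm)
  expect_equal(as.matrix(twice), as.matrix(m))
  # strength multiset invariant under arbitrary permutation
  local_seed_eval(3, {
    p <- sample(6)
    mp <- reorder_nodes(m, p)
    expect_equal(sort(node_strength(mp)), sort(node_strength(m)))
    expect_equal(node_labels(mp), node_labels(m)[p])
  })
  expect_error(reorder_nodes(m, c(1, 1, 2, 3, 4, 5)), "permutation")
})

test_that("dataset construction enforces shared shape and unique subjects", {
  d <- tiny_dataset(N = 5, n = 8)
  expect_s3_class(d, "connectome_dataset")
  expect_length(d, 5)
  bad_scores <- d$scores
  bad_scores$subject_id[2] <- bad_scores$subject_id[1]
  expect_error(connectome_dataset(d$matrices, bad_scores), "duplicate")
  expect_error(connectome_dataset(c(d$matrices[1:4],
                                    list(random_cm(9, seed = 1))),
                                  d$scores),
               "node count")
  expect_error(connectome_dataset(list(), d$scores[0, ]), "empty")
})

test_that("save/load round-trips a dataset through plain-text files", {
  d <- tiny_dataset(N = 6, n = 7, seed = 11)
  dir <- withr_local_tempdir()
  manifest <- save_dataset(d, dir)
  expect_true(file.exists(manifest))
  d2 <- read_dataset(dir)
  expect_identical(d2$scores$subject_id, d$scores$subject_id)
  expect_equal(d2$scores$score, d$scores$score, tolerance = 1e-15)
  for (k in seq_along(d$matrices)) {
    a <- as.matrix(d$matrices[[k]]); b <- as.matrix(d2$matrices[[k]])
    expect_lt(max(abs(a - b)) / max(abs(a)), 1e-12)
  }
})

test_that("loader errors name the offending subject or cell", {
  d <- tiny_dataset(N = 3, n = 6, seed = 12)
  dir <- withr_local_tempdir()
  save_dataset(d, dir)
  # missing matrix file
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  paths <- stats::setNames(file.path(dir, unlist(man$subjects)),
                           names(man$subjects))
  bad <- paths
  file.remove(bad[[2]])
  expect_error(load_dataset(bad, file.path(dir, "scores.csv")),
               d$scores$subject_id[2])
  # nonzero diagonal flagged by validation
  dir2 <- withr_local_tempdir()
  save_dataset(d[1], dir2)
  f <- list.files(dir2, pattern = "^matrix_", full.names = TRUE)[1]
  lines <- readLines(f)
  cells <- strsplit(lines[1], ",")[[1]]
  cells[1] <- "0.1"
  writeLines(c(paste(cells, collapse = ","), lines[-1]), f)
  expect_error(read_dataset(dir2), "nonzero diagonal")
})
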