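# Minimal reverse-mode network machinery for the BrainNetCNN-style
# architectures used by the GAN. Layers are plain lists; a network is a list
# of layers plus shape metadata. Everything is single-threaded base R:
# the matrices involved are small (tens of nodes, tens of channels), so
# structured matrix products beat any generic autodiff here.
#
# Shapes flowing through a network:
#   input            n x n matrix, promoted to an n x n x 1 array
#   e2e              n x n x c_in  -> n x n x c_out
#   e2n              n x n x c_in  -> n x c_out
#   flatten          any           -> numeric vector
#   dense            vector        -> vector
#   act / dropout    shape-preserving

lrelu_slope <- 0.2

nn_act <- function(x, fun) {
  switch(fun,
         lrelu = x * (lrelu_slope + (1 - lrelu_slope) * (x > 0)),
         softplus = log1p(exp(pmin(x, 30))) + pmax(x - 30, 0),
         linear = x,
         stop("unknown activation ", fun))
}

nn_act_grad <- function(x, fun) {
  switch(fun,
         lrelu = lrelu_slope + (1 - lrelu_slope) * (x > 0),
         softplus = 1 / (1 + exp(-x)),
         linear = rep(1, length(x)),
         stop("unknown activation ", fun))
}

layer_e2e <- function(n, c_in, c_out) {
  sd <- sqrt(2 / (2 * n * c_in))
  list(type = "e2e", n = n, c_in = c_in, c_out = c_out,
       rw = array(stats::rnorm(n * c_in * c_out, 0, sd), c(n, c_in, c_out)),
       cw = array(stats::rnorm(n * c_in * c_out, 0, sd), c(n, c_in, c_out)),
       b = numeric(c_out))
}

layer_e2n <- function(n, c_in, c_out) {
  sd <- sqrt(2 / (2 * n * c_in))
  list(type = "e2n", n = n, c_in = c_in, c_out = c_out,
       rw = array(stats::rnorm(n * c_in * c_out, 0, sd), c(n, c_in, c_out)),
       cw = array(stats::rnorm(n * c_in * c_out, 0, sd), c(n, c_in, c_out)),
       b = numeric(c_out))
}

layer_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

layer_act <- function(fun) list(type = "act", fun = fun)
layer_dropout <- function(p) list(type = "dropout", p = p)
layer_flatten <- function() list(type = "flatten")

new_network <- function(layers, n_nodes = NA_integer_, role = "network") {
  structure(list(layers = layers, n_nodes = n_nodes, role = role),
            class = "brainnet_network")
}

# promote a plain matrix input to the canonical n x n x 1 array
as_input_array <- function(x) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), 1L)) else x
}

# Forward pass. train toggles dropout; masks (list indexed by layer) can be
# supplied to pin dropout noise, which the gradient-penalty evaluation needs
# when re-running the critic at perturbed inputs.
nn_forward <- function(net, x, train = FALSE, masks = NULL) {
  a <- as_input_array(x)
  L <- length(net$layers)
  cache <- vector("list", L)
  used_masks <- vector("list", L)
  for (l in seq_len(L)) {
    layer <- net$layers[[l]]
    switch(layer$type,
      e2e = {
        n <- layer$n; c_in <- layer$c_in; c_out <- layer$c_out
        Aflat <- matrix(a, n, n * c_in)
        At <- matrix(aperm(a, c(2L, 1L, 3L)), n, n * c_in)
        RV <- Aflat %*% matrix(layer$rw, n * c_in, c_out)
        CV <- At %*% matrix(layer$cw, n * c_in, c_out)
        out <- array(0, c(n, n, c_out))
        for (o in seq_len(c_out))
          out[, , o] <- RV[, o] + rep(CV[, o], each = n) + layer$b[o]
        cache[[l]] <- list(Aflat = Aflat, At = At)
        a <- out
      },
      e2n = {
        n <- layer$n; c_in <- layer$c_in; c_out <- layer$c_out
        Aflat <- matrix(a, n, n * c_in)
        At <- matrix(aperm(a, c(2L, 1L, 3L)), n, n * c_in)
        out <- Aflat %*% matrix(layer$rw, n * c_in, c_out) +
          At %*% matrix(layer$cw, n * c_in, c_out)
        out <- sweep(out, 2L, layer$b, "+")
        cache[[l]] <- list(Aflat = Aflat, At = At)
        a <- out
      },
      flatten = {
        cache[[l]] <- list(dims = dim(a) %||% length(a))
        a <- as.numeric(a)
      },
      dense = {
        cache[[l]] <- list(x = a)
        a <- as.numeric(a %*% layer$W) + layer$b
      },
      act = {
        cache[[l]] <- list(pre = a)
        dims <- dim(a)
        a <- nn_act(a, layer$fun)
        if (!is.null(dims)) dim(a) <- dims
      },
      dropout = {
        if (train && layer$p > 0) {
          m <- if (!is.null(masks) && !is.null(masks[[l]])) masks[[l]]
               else (stats::runif(length(a)) >= layer$p) / (1 - layer$p)
          used_masks[[l]] <- m
          dims <- dim(a)
          a <- a * m
          if (!is.null(dims)) dim(a) <- dims
        }
        cache[[l]] <- NULL
      },
      stop("unknown layer type ", layer$type))
  }
  list(out = a, cache = cache, masks = used_masks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Backward pass from an upstream gradient g (same shape as the output).
# Returns per-layer parameter gradients and the gradient w.r.t. the input
# (as an n x n matrix when the input was one).
nn_backward <- function(net, fwd, g, input_was_matrix = TRUE) {
  L <- length(net$layers)
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    layer <- net$layers[[l]]
    switch(layer$type,
      e2e = {
        n <- layer$n; c_in <- layer$c_in; c_out <- layer$c_out
        Aflat <- fwd$cache[[l]]$Aflat; At <- fwd$cache[[l]]$At
        Gm <- matrix(g, n * n, c_out)
        GR <- matrix(0, n, c_out); GC <- matrix(0, n, c_out)
        for (o in seq_len(c_out)) {
          Go <- matrix(Gm[, o], n, n)
          GR[, o] <- rowSums(Go)
          GC[, o] <- colSums(Go)
        }
        grads[[l]] <- list(
          rw = array(crossprod(Aflat, GR), c(n, c_in, c_out)),
          cw = array(crossprod(At, GC), c(n, c_in, c_out)),
          b = colSums(Gm))
        gin <- array(0, c(n, n, c_in))
        for (ci in seq_len(c_in)) {
          rwci <- matrix(layer$rw[, ci, ], n, c_out)
          cwci <- matrix(layer$cw[, ci, ], n, c_out)
          gin[, , ci] <- GR %*% t(rwci) + cwci %*% t(GC)
        }
        g <- gin
      },
      e2n = {
        n <- layer$n; c_in <- layer$c_in; c_out <- layer$c_out
        Aflat <- fwd$cache[[l]]$Aflat; At <- fwd$cache[[l]]$At
        Gm <- matrix(g, n, c_out)
        grads[[l]] <- list(
          rw = array(crossprod(Aflat, Gm), c(n, c_in, c_out)),
          cw = array(crossprod(At, Gm), c(n, c_in, c_out)),
          b = colSums(Gm))
        gin <- array(0, c(n, n, c_in))
        for (ci in seq_len(c_in)) {
          rwci <- matrix(layer$rw[, ci, ], n, c_out)
          cwci <- matrix(layer$cw[, ci, ], n, c_out)
          gin[, , ci] <- Gm %*% t(rwci) + cwci %*% t(Gm)
        }
        g <- gin
      },
      flatten = {
        dims <- fwd$cache[[l]]$dims
        if (length(dims) > 1L) dim(g) <- dims
      },
      dense = {
        x <- fwd$cache[[l]]$x
        gv <- as.numeric(g)
        grads[[l]] <- list(W = outer(as.numeric(x), gv), b = gv)
        g <- as.numeric(layer$W %*% gv)
      },
      act = {
        pre <- fwd$cache[[l]]$pre
        dims <- dim(pre)
        g <- g * nn_act_grad(pre, layer$fun)
        if (!is.null(dims)) dim(g) <- dims
      },
      dropout = {
        m <- fwd$masks[[l]]
        if (!is.null(m)) {
          dims <- dim(g)
          g <- g * m
          if (!is.null(dims)) dim(g) <- dims
        }
      })
  }
  if (input_was_matrix && length(dim(g)) == 3L && dim(g)[3L] == 1L)
    g <- g[, , 1L]
  list(grads = grads, gin = g)
}

param_names <- c("rw", "cw", "b", "W")

# elementwise accumulate: a + scale * b over matching parameter lists
acc_grads <- function(a, b, scale = 1) {
  if (is.null(a)) {
    if (scale == 1) return(b)
    return(lapply(b, function(lyr)
      if (is.null(lyr)) NULL else lapply(lyr, function(p) p * scale)))
  }
  for (l in seq_along(b)) {
    if (is.null(b[[l]])) next
    if (is.null(a[[l]])) {
      a[[l]] <- lapply(b[[l]], function(p) p * scale)
    } else {
      for (k in names(b[[l]]))
        a[[l]][[k]] <- a[[l]][[k]] + scale * b[[l]][[k]]
    }
  }
  a
}

adam_init <- function(net) {
  st <- list(t = 0L, m = vector("list", length(net$layers)),
             v = vector("list", length(net$layers)))
  for (l in seq_along(net$layers)) {
    layer <- net$layers[[l]]
    keep <- intersect(param_names, names(layer))
    if (length(keep)) {
      st$m[[l]] <- lapply(layer[keep], function(p) p * 0)
      st$v[[l]] <- lapply(layer[keep], function(p) p * 0)
    }
  }
  st
}

adam_step <- function(net, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (l in seq_along(net$layers)) {
    if (is.null(grads[[l]]) || is.null(st$m[[l]])) next
    for (k in names(st$m[[l]])) {
      gk <- grads[[l]][[k]]
      st$m[[l]][[k]] <- beta1 * st$m[[l]][[k]] + (1 - beta1) * gk
      st$v[[l]][[k]] <- beta2 * st$v[[l]][[k]] + (1 - beta2) * gk * gk
      net$layers[[l]][[k]] <- net$layers[[l]][[k]] -
        lr * (st$m[[l]][[k]] / bc1) / (sqrt(st$v[[l]][[k]] / bc2) + eps)
    }
  }
  list(net = net, state = st)
}

# fast symmetric embedding of a lower-triangle edge vector (no validation;
# used in the inner training loop where the decoder output is already >= 0)
edgevec_to_matrix <- function(v, n) {
  w <- matrix(0, n, n)
  tw <- t(w)
  tw[upper.tri(tw)] <- v
  w <- t(tw)
  w + t(w)
}

# backward of edgevec_to_matrix: each edge feeds (i,j) and (j,i)
matrix_grad_to_edgevec <- function(G) {
  Gs <- G + t(G)
  t(Gs)[upper.tri(Gs)]
}
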