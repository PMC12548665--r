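#' BrainNetCNN convolution primitives
#'
#' The three adjacency-matrix convolutions used throughout the generative
#' model, in their single-filter form. An edge-to-edge (E2E) filter has a
#' cross-shaped receptive field: the output at `(i, j)` is the
#' `row_weights`-weighted sum of row `i` plus the `col_weights`-weighted sum
#' of column `j`,
#' \deqn{out(i,j) = \sum_k r_k x(i,k) + \sum_k c_k x(k,j) + b.}
#' An edge-to-node (E2N) filter reduces each node's incident edges to one
#' value, \eqn{out(i) = \sum_j r_j x(i,j) + \sum_j c_j x(j,i) + b}, and a
#' node-to-graph (N2G) filter pools a node vector to a scalar weighted sum.
#' All three are linear in the input when the bias is zero.
#'
#' @param x square numeric matrix (E2E/E2N) .
#' @param row_weights,col_weights numeric weight vectors of length
#'   `nrow(x)`.
#' @param bias scalar bias.
#' @return `e2e_apply()`: a matrix of the same shape; `e2n_apply()`: a
#'   length-n vector; `n2g_apply()`: a scalar.
#' @examples
#' x <- matrix(c(0, 1, 1, 0), 2, 2)
#' e2n_apply(x, c(1, 1), c(1, 1))  # c(2, 2)
#' @export
e2e_apply <- function(x, row_weights, col_weights, bias = 0) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("'x' must be a square matrix", call. = FALSE)
  n <- nrow(x)
  stopifnot(length(row_weights) == n, length(col_weights) == n)
  rv <- as.numeric(x %*% row_weights)
  cv <- as.numeric(crossprod(x, col_weights))
  matrix(rv, n, n) + matrix(cv, n, n, byrow = TRUE) + bias
}

#' @rdname e2e_apply
#' @export
e2n_apply <- function(x, row_weights, col_weights, bias = 0) {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop("'x' must be a square matrix", call. = FALSE)
  n <- nrow(x)
  stopifnot(length(row_weights) == n, length(col_weights) == n)
  as.numeric(x %*% row_weights) + as.numeric(crossprod(x, col_weights)) + bias
}

#' @rdname e2e_apply
#' @param v numeric node-value vector (N2G input).
#' @param weights numeric weight vector, same length as `v`.
#' @export
n2g_apply <- function(v, weights, bias = 0) {
  if (length(v) != length(weights))
    stop("'v' and 'weights' must have the same length", call. = FALSE)
  sum(v * weights) + bias
}

#' Architecture hyperparameters for the GAN networks
#'
#' Describes the four network roles. Encoder, critic and regressor share a
#' four-layer convolutional stack (E2E, E2E, E2N, N2G); the encoder adds two
#' fully connected layers down to `latent_dim`, the critic a single linear
#' scalar head (no output activation, as Wasserstein estimation requires),
#' and the regressor four fully connected layers down to a scalar. The
#' decoder is a five-layer multilayer perceptron from the latent vector to
#' the `n(n-1)/2` lower-triangle edge vector, with a softplus final
#' activation so synthesized edge weights are non-negative. Hidden
#' activations are leaky rectifiers (slope 0.2); dropout at rate `dropout_p`
#' follows every convolutional and hidden fully connected block of the
#' encoder, critic and regressor (the decoder has none).
#'
#' @param n_nodes number of brain regions.
#' @param latent_dim latent-space dimensionality.
#' @param e2e_channels channel widths of the two E2E layers.
#' @param e2n_channels channels of the E2N layer.
#' @param n2g_units units of the N2G pooling layer.
#' @param fc_widths_encoder two fully connected widths; the last must equal
#'   `latent_dim`.
#' @param fc_widths_decoder five fully connected widths; the last must equal
#'   `n_nodes (n_nodes - 1) / 2`.
#' @param fc_widths_regressor four fully connected widths ending in 1.
#' @param dropout_p dropout rate in `[0, 1)`.
#' @return list of class `"network_spec"`.
#' @export
network_spec <- function(n_nodes, latent_dim = 64,
                         e2e_channels = c(32, 64), e2n_channels = 128,
                         n2g_units = 256,
                         fc_widths_encoder = NULL,
                         fc_widths_decoder = NULL,
                         fc_widths_regressor = NULL,
                         dropout_p = 0.1) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 3, latent_dim >= 1, length(e2e_channels) == 2,
            all(e2e_channels >= 1), e2n_channels >= 1, n2g_units >= 1,
            dropout_p >= 0, dropout_p < 1)
  E <- n_nodes * (n_nodes - 1) / 2
  if (is.null(fc_widths_encoder))
    fc_widths_encoder <- c(max(2 * latent_dim, 32), latent_dim)
  if (is.null(fc_widths_decoder))
    fc_widths_decoder <- c(max(2 * latent_dim, 64), 128, 256, 256, E)
  if (is.null(fc_widths_regressor))
    fc_widths_regressor <- c(128, 64, 32, 1)
  if (length(fc_widths_encoder) != 2 ||
      fc_widths_encoder[2] != latent_dim)
    stop("fc_widths_encoder must have length 2 and end in latent_dim",
         call. = FALSE)
  if (length(fc_widths_decoder) != 5 || fc_widths_decoder[5] != E)
    stop(sprintf(
      "fc_widths_decoder must have length 5 and end in n(n-1)/2 = %d", E),
      call. = FALSE)
  if (length(fc_widths_regressor) != 4 || fc_widths_regressor[4] != 1)
    stop("fc_widths_regressor must have length 4 and end in 1", call. = FALSE)
  if (any(c(fc_widths_encoder, fc_widths_decoder, fc_widths_regressor) < 1))
    stop("all layer widths must be positive", call. = FALSE)
  structure(list(n_nodes = n_nodes, latent_dim = as.integer(latent_dim),
                 e2e_channels = as.integer(e2e_channels),
                 e2n_channels = as.integer(e2n_channels),
                 n2g_units = as.integer(n2g_units),
                 fc_widths_encoder = as.integer(fc_widths_encoder),
                 fc_widths_decoder = as.integer(fc_widths_decoder),
                 fc_widths_regressor = as.integer(fc_widths_regressor),
                 dropout_p = dropout_p),
            class = "network_spec")
}

# shared E2E -> E2E -> E2N -> N2G stack; dropout optionally after each block
conv_stack_layers <- function(spec, dropout = TRUE) {
  n <- spec$n_nodes
  p <- if (dropout) spec$dropout_p else 0
  layers <- list(
    layer_e2e(n, 1L, spec$e2e_channels[1]), layer_act("lrelu"),
    layer_dropout(p),
    layer_e2e(n, spec$e2e_channels[1], spec$e2e_channels[2]),
    layer_act("lrelu"), layer_dropout(p),
    layer_e2n(n, spec$e2e_channels[2], spec$e2n_channels),
    layer_act("lrelu"), layer_dropout(p),
    layer_flatten(),
    layer_dense(n * spec$e2n_channels, spec$n2g_units),  # N2G pooling
    layer_act("lrelu"), layer_dropout(p))
  layers
}

#' Build the four GAN networks from a spec
#'
#' Parameters are initialized from the current RNG state (He-scaled
#' normals), so wrap calls in `set.seed()` for reproducible builds.
#' `build_encoder()` maps an `n x n` matrix to a `latent_dim` vector,
#' `build_decoder()` a latent vector to a non-negative edge vector,
#' `build_critic()` a matrix to an unbounded scalar score, and
#' `build_regressor()` a matrix to a scalar cognitive-score prediction.
#'
#' @param spec a [network_spec()].
#' @return object of class `"brainnet_network"`.
#' @export
build_encoder <- function(spec) {
  layers <- conv_stack_layers(spec)
  layers <- c(layers, list(
    layer_dense(spec$n2g_units, spec$fc_widths_encoder[1]),
    layer_act("lrelu"), layer_dropout(spec$dropout_p),
    layer_dense(spec$fc_widths_encoder[1], spec$fc_widths_encoder[2])))
  new_network(layers, spec$n_nodes, "encoder")
}

#' @rdname build_encoder
#' @export
build_decoder <- function(spec) {
  w <- spec$fc_widths_decoder
  layers <- list(layer_dense(spec$latent_dim, w[1]), layer_act("lrelu"))
  for (k in 2:5)
    layers <- c(layers, list(layer_dense(w[k - 1], w[k]),
                             layer_act(if (k == 5) "softplus" else "lrelu")))
  new_network(layers, spec$n_nodes, "decoder")
}

#' @rdname build_encoder
#' @export
build_critic <- function(spec) {
  layers <- c(conv_stack_layers(spec),
              list(layer_dense(spec$n2g_units, 1L)))  # linear head
  new_network(layers, spec$n_nodes, "critic")
}

#' @rdname build_encoder
#' @export
build_regressor <- function(spec) {
  w <- spec$fc_widths_regressor
  layers <- conv_stack_layers(spec)
  layers <- c(layers, list(
    layer_dense(spec$n2g_units, w[1]), layer_act("lrelu"),
    layer_dropout(spec$dropout_p),
    layer_dense(w[1], w[2]), layer_act("lrelu"),
    layer_dropout(spec$dropout_p),
    layer_dense(w[2], w[3]), layer_act("lrelu"),
    layer_dense(w[3], w[4])))
  new_network(layers, spec$n_nodes, "regressor")
}

#' Evaluate a network in inference mode
#'
#' Runs a forward pass with dropout disabled; repeated calls on the same
#' input are bit-identical.
#'
#' @param object a `brainnet_network`.
#' @param x input matrix (encoder/critic/regressor) or latent vector
#'   (decoder).
#' @param ... ignored.
#' @export
predict.brainnet_network <- function(object, x, ...) {
  nn_forward(object, x, train = FALSE)$out
}

#' @export
print.brainnet_network <- function(x, ...) {
  types <- vapply(x$layers, `[[`, "", "type")
  np <- sum(vapply(x$layers, function(l)
    sum(vapply(intersect(param_names, names(l)),
               function(k) length(l[[k]]), 1)), 1))
  cat(sprintf("BrainNet network (%s): %d layers [%s], %d parameters\n",
              x$role, length(x$layers), paste(types, collapse = ", "), np))
  invisible(x)
}

#' Diagnostic linear critic
#'
#' Builds a critic whose output is the inner product `sum(W * x)` with a
#' fixed weight matrix. Its input gradient is exactly `W` everywhere, so the
#' gradient penalty has the closed form `(||W||_F - 1)^2`; useful for
#' validating Lipschitz-penalty computations.
#'
#' @param weights numeric matrix of critic weights.
#' @return a `brainnet_network`.
#' @export
linear_critic <- function(weights) {
  stopifnot(is.matrix(weights))
  d <- layer_dense(length(weights), 1L)
  d$W <- matrix(as.numeric(weights), ncol = 1L)
  d$b <- 0
  new_network(list(layer_flatten(), d), nrow(weights), "critic")
}
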