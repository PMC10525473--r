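# Compact feed-forward network engine: ReLU hidden layers, sigmoid output,
# binary cross-entropy, mini-batch Adam, optional inverted dropout.  Small
# dense nets on 8 input features; everything is plain matrix algebra.

#' Describe a feed-forward network architecture
#'
#' @param layer_sizes Integer vector of node counts from input to output;
#'   the input layer must have 8 nodes (the cohort's feature columns) and
#'   the output 1 node (sigmoid probability of the diabetic class).
#' @param dropout_rate Dropout fraction applied (inverted dropout, training
#'   only) after the hidden layers listed in `dropout_layers`.
#' @param dropout_layers Indices (1 = first hidden layer) that carry
#'   dropout.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(layer_sizes, dropout_rate = 0,
                         dropout_layers = integer(0)) {
  layer_sizes <- as.integer(layer_sizes)
  stopifnot(length(layer_sizes) >= 2,
            layer_sizes[1] == 8L,
            layer_sizes[length(layer_sizes)] == 1L,
            dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(layer_sizes = layer_sizes,
         dropout_rate = dropout_rate,
         dropout_layers = as.integer(dropout_layers),
         hidden_activation = "relu",
         output_activation = "sigmoid"),
    class = "network_spec"
  )
}

#' The loop classifier architecture
#'
#' The small network trained for five epochs inside every shuffle-train
#' cycle: hidden layers of 16, 64 and 32 nodes, ReLU after each, sigmoid
#' output, no dropout.
#'
#' @return A [network_spec()] with sizes 8-16-64-32-1.
#' @export
build_loop_network <- function() {
  network_spec(c(8L, 16L, 64L, 32L, 1L))
}

#' The independent evaluation network architecture
#'
#' The deeper network used to judge the selected dataset from scratch:
#' hidden layers of 16, 64, 32 and 16 nodes with dropout 0.2 after the
#' first three (dropout precedes the ReLU in the layer order; with ReLU
#' the two orders are equivalent), sigmoid output.
#'
#' @return A [network_spec()] with sizes 8-16-64-32-16-1 and dropout 0.2.
#' @export
build_eval_network <- function() {
  network_spec(c(8L, 16L, 64L, 32L, 16L, 1L),
               dropout_rate = 0.2, dropout_layers = 1:3)
}

#' Number of trainable parameters of a network
#'
#' @param spec A [network_spec()].
#' @return Total count of weights and biases.
#' @export
n_parameters <- function(spec) {
  sz <- spec$layer_sizes
  sum(sz[-length(sz)] * sz[-1] + sz[-1])
}

init_params <- function(spec, seed = NULL) {
  sz <- spec$layer_sizes
  with_seed_(seed, {
    lapply(seq_len(length(sz) - 1L), function(l) {
      fan_in <- sz[l]
      list(W = matrix(stats::rnorm(fan_in * sz[l + 1], sd = sqrt(2 / fan_in)),
                      fan_in, sz[l + 1]),
           b = numeric(sz[l + 1]))
    })
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass. training = TRUE applies inverted dropout with fresh masks
# from the current RNG state and returns the caches needed for backprop.
mlp_forward <- function(params, X, spec, training = FALSE) {
  L <- length(params)
  A <- X
  caches <- if (training) vector("list", L)
  for (l in seq_len(L)) {
    Z <- A %*% params[[l]]$W
    Z <- sweep(Z, 2, params[[l]]$b, "+")
    if (l < L) {
      H <- Z * (Z > 0)
      mask <- NULL
      if (training && spec$dropout_rate > 0 && l %in% spec$dropout_layers) {
        keep <- 1 - spec$dropout_rate
        mask <- matrix(stats::runif(length(H)) < keep, nrow(H), ncol(H)) / keep
        H <- H * mask
      }
      if (training) caches[[l]] <- list(A_prev = A, Z = Z, mask = mask)
      A <- H
    } else {
      if (training) caches[[l]] <- list(A_prev = A, Z = Z)
      A <- sigmoid(Z)
    }
  }
  if (training) list(prob = A, caches = caches) else A
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# One backward pass; returns gradients in the shape of params.
mlp_backward <- function(params, fwd, y) {
  L <- length(params)
  m <- length(y)
  grads <- vector("list", L)
  dZ <- (fwd$prob - y) / m                      # sigmoid + BCE shortcut
  for (l in L:1) {
    cache <- fwd$caches[[l]]
    grads[[l]] <- list(W = crossprod(cache$A_prev, dZ),
                       b = colSums(dZ))
    if (l > 1) {
      dA <- dZ %*% t(params[[l]]$W)
      if (!is.null(fwd$caches[[l - 1]]$mask)) dA <- dA * fwd$caches[[l - 1]]$mask
      dZ <- dA * (fwd$caches[[l - 1]]$Z > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, t, lr = 1e-3,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (l in seq_along(params)) {
    st <- state[[l]]; g <- grads[[l]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    params[[l]]$W <- params[[l]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    params[[l]]$b <- params[[l]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[l]] <- st
  }
  list(params = params, state = state)
}

cohort_xy <- function(data) {
  assert_cohort(data)
  list(X = as.matrix(data[, feature_columns()]),
       y = as.numeric(data$label))
}

#' Train a feed-forward classifier on a cohort table
#'
#' Minimizes binary cross-entropy by mini-batch Adam (learning rate 1e-3,
#' batch size 256 by default); hidden activations are ReLU, the output a
#' sigmoid. Deterministic given `seed` (weight initialization, batch order
#' and dropout masks all derive from it).
#'
#' @param spec A [network_spec()].
#' @param train Training cohort tibble (feature columns plus `label`).
#' @param val Optional validation cohort tibble tracked per epoch.
#' @param epochs Number of passes over the training data.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param init Optional parameter list from a previous `mlp_fit` to resume
#'   training from instead of fresh random initialization.
#' @return An object of class `mlp_fit`: the spec, fitted parameters and a
#'   per-epoch `history` tibble (loss and accuracy on train and, when
#'   given, validation data).
#' @export
train_network <- function(spec, train, val = NULL, epochs = 5, seed = NULL,
                          lr = 1e-3, batch_size = 256, init = NULL) {
  stopifnot(inherits(spec, "network_spec"), is_count(epochs))
  tr <- cohort_xy(train)
  vl <- if (!is.null(val) && nrow(val) > 0) cohort_xy(val)
  n <- nrow(tr$X)
  if (n == 0) stop("empty training set", call. = FALSE)

  history <- vector("list", epochs)
  with_seed_(seed, {
    params <- init %||% init_params(spec)
    opt <- adam_init(params)
    t <- 0L
    for (epoch in seq_len(epochs)) {
      order <- sample.int(n)
      for (first in seq(1L, n, by = batch_size)) {
        idx <- order[first:min(first + batch_size - 1L, n)]
        fwd <- mlp_forward(params, tr$X[idx, , drop = FALSE], spec,
                           training = TRUE)
        if (!all(is.finite(fwd$prob))) {
          stop("non-finite network output at epoch ", epoch, call. = FALSE)
        }
        grads <- mlp_backward(params, fwd, tr$y[idx])
        t <- t + 1L
        stepped <- adam_step(params, grads, opt, t, lr = lr)
        params <- stepped$params
        opt <- stepped$state
      }
      p_tr <- mlp_forward(params, tr$X, spec)
      row <- tibble::tibble(
        epoch = epoch,
        train_loss = bce_loss(p_tr, tr$y),
        train_accuracy = mean((p_tr > 0.5) == (tr$y > 0.5))
      )
      if (!is.null(vl)) {
        p_vl <- mlp_forward(params, vl$X, spec)
        row$val_loss <- bce_loss(p_vl, vl$y)
        row$val_accuracy <- mean((p_vl > 0.5) == (vl$y > 0.5))
      }
      history[[epoch]] <- row
    }
    structure(
      list(spec = spec, params = params,
           history = dplyr::bind_rows(history),
           epochs = epochs, seed = seed),
      class = "mlp_fit"
    )
  })
}

#' Predict from a fitted classifier
#'
#' @param object An `mlp_fit`.
#' @param newdata Cohort tibble with the eight feature columns.
#' @param type `"prob"` for sigmoid scores, `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return Numeric (or integer for `"class"`) vector, one value per row.
#' @export
predict.mlp_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, feature_columns()])
  p <- as.numeric(mlp_forward(object$params, X, object$spec))
  if (type == "class") as.integer(p > 0.5) else p
}

#' Classification accuracy of a fit on a cohort table
#'
#' @param fit An `mlp_fit`.
#' @param data Cohort tibble with feature columns and `label`.
#' @return Fraction of rows classified correctly at threshold 0.5.
#' @export
accuracy <- function(fit, data) {
  mean(predict(fit, data, type = "class") == (data$label > 0.5))
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat("<mlp_fit>", paste(x$spec$layer_sizes, collapse = "-"),
      "|", n_parameters(x$spec), "parameters |", x$epochs, "epochs\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("final train accuracy %.4f%s\n", last$train_accuracy,
                if (!is.null(last$val_accuracy))
                  sprintf(", val accuracy %.4f", last$val_accuracy) else ""))
  }
  invisible(x)
}
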