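#' Training configuration for the feed-forward classifier
#'
#' Full-batch gradient descent on the cross-entropy loss with classical
#' momentum. A seeded fraction of the training data is held out for
#' validation; training stops when the validation loss has not improved for
#' `patience` consecutive epochs (or at `max_epochs`), and the weights from
#' the best validation epoch are returned.
#'
#' @param learning_rate Step size, default 0.01.
#' @param momentum Momentum coefficient in `[0, 1)`, default 0.9.
#' @param max_epochs Epoch cap, default 5000.
#' @param patience Epochs without validation improvement before stopping,
#'   default 100. `patience = 0` stops at the first non-improving epoch.
#' @param val_fraction Fraction of samples held out for validation, default 0.15.
#' @param seed Seed for the validation split (weight initialization is seeded
#'   separately in [ann_init()]).
#' @return A list of class `ann_config`.
#' @export
ann_config <- function(learning_rate = 0.01, momentum = 0.9,
                       max_epochs = 5000L, patience = 100L,
                       val_fraction = 0.15, seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("`momentum` must be in [0, 1)", call. = FALSE)
  if (max_epochs < 1) stop("`max_epochs` must be >= 1", call. = FALSE)
  if (patience < 0) stop("`patience` must be >= 0", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1) stop("`val_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "ann_config")
}

#' Initialize a three-layer feed-forward network
#'
#' Architecture 512 -> 25 -> 7 by default: sigmoid hidden layer, softmax
#' output layer. All weights and biases are drawn uniformly from
#' `[-0.5, 0.5]` with the given seed; the same seed reproduces the model
#' bit for bit.
#'
#' @param seed Integer seed for the weight draw.
#' @param n_in,n_hidden,n_out Layer sizes (defaults 512, 25, 7).
#' @return A list of class `ann_model` with `w1` (`n_hidden x n_in`), `b1`,
#'   `w2` (`n_out x n_hidden`), `b2`.
#' @export
ann_init <- function(seed = 1L, n_in = 512L, n_hidden = 25L, n_out = 7L) {
  set.seed(seed)
  structure(list(
    w1 = matrix(stats::runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
    b1 = stats::runif(n_hidden, -0.5, 0.5),
    w2 = matrix(stats::runif(n_out * n_hidden, -0.5, 0.5), n_out, n_hidden),
    b2 = stats::runif(n_out, -0.5, 0.5),
    n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
    n_out = as.integer(n_out)), class = "ann_model")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass on an n x n_in matrix; returns hidden activations and
# row-wise softmax probabilities.
ann_forward_full <- function(model, x) {
  hidden <- sigmoid(sweep(tcrossprod(x, model$w1), 2L, model$b1, "+"))
  logits <- sweep(tcrossprod(hidden, model$w2), 2L, model$b2, "+")
  logits <- logits - apply(logits, 1L, max)  # shift-invariant, stable
  e <- exp(logits)
  list(hidden = hidden, probs = e / rowSums(e))
}

#' Class probabilities for feature vectors
#'
#' Sigmoid hidden layer followed by a softmax output layer; each row of the
#' result is strictly positive and sums to 1.
#'
#' @param model An `ann_model`.
#' @param x A feature vector of length `n_in` or an `n x n_in` matrix.
#' @return A probability vector of length `n_out`, or an `n x n_out` matrix.
#' @export
ann_forward <- function(model, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, 1L)
  if (ncol(x) != model$n_in) {
    stop(sprintf("feature length %d does not match the %d network inputs",
                 ncol(x), model$n_in), call. = FALSE)
  }
  if (!all(is.finite(x))) stop("features must be finite", call. = FALSE)
  p <- ann_forward_full(model, x)$probs
  if (single) drop(p) else p
}

# Cross-entropy loss and analytic gradients for a labelled batch.
# `labels` are 1-based class indices.
ann_loss_grad <- function(model, x, labels, want_grad = TRUE) {
  n <- nrow(x)
  fwd <- ann_forward_full(model, x)
  p <- pmax(fwd$probs, 1e-300)
  loss <- -mean(log(p[cbind(seq_len(n), labels)]))
  if (!want_grad) return(list(loss = loss))
  dz2 <- fwd$probs
  dz2[cbind(seq_len(n), labels)] <- dz2[cbind(seq_len(n), labels)] - 1
  dz2 <- dz2 / n
  dw2 <- crossprod(dz2, fwd$hidden)
  db2 <- colSums(dz2)
  dh <- dz2 %*% model$w2
  dz1 <- dh * fwd$hidden * (1 - fwd$hidden)
  dw1 <- crossprod(dz1, x)
  db1 <- colSums(dz1)
  list(loss = loss, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

#' Train the classifier by backpropagation
#'
#' Full-batch gradient descent with momentum on the cross-entropy loss.
#' A seeded `val_fraction` of the samples is held out; after every epoch the
#' validation loss is recorded and the best-scoring weights are kept. Training
#' stops when validation has not improved for `patience` epochs or at
#' `max_epochs`, and the best weights are returned.
#'
#' @param model An `ann_model` from [ann_init()].
#' @param features `n x n_in` numeric matrix (one feature vector per row).
#' @param labels Integer class labels in `1..n_out` (or a factor).
#' @param cfg An [ann_config()].
#' @return An object of class `ann_fit`: list with `model` (best weights),
#'   `history` (tibble of epoch, train_loss, val_loss), `best_epoch`,
#'   `best_val_loss`, `stopped_epoch`, `config`.
#' @export
ann_train <- function(model, features, labels, cfg = ann_config()) {
  if (is.factor(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  if (!is.matrix(features) || nrow(features) != length(labels)) {
    stop("`features` must be a matrix with one row per label", call. = FALSE)
  }
  if (ncol(features) != model$n_in) {
    stop(sprintf("feature length %d does not match the %d network inputs",
                 ncol(features), model$n_in), call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop(lesiontex_error("degenerate_labels",
                         "training data contains fewer than two classes"))
  }
  if (any(labels < 1L | labels > model$n_out)) {
    stop(sprintf("labels must lie in 1..%d", model$n_out), call. = FALSE)
  }
  n <- nrow(features)
  set.seed(cfg$seed)
  n_val <- max(1L, floor(cfg$val_fraction * n))
  if (n_val >= n) stop("validation split leaves no training samples", call. = FALSE)
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(labels[tr_idx])) < 2L) {
    stop(lesiontex_error("degenerate_labels",
                         "training portion of the split contains fewer than two classes"))
  }
  xt <- features[tr_idx, , drop = FALSE]; yt <- labels[tr_idx]
  xv <- features[val_idx, , drop = FALSE]; yv <- labels[val_idx]

  vel <- list(w1 = model$w1 * 0, b1 = model$b1 * 0,
              w2 = model$w2 * 0, b2 = model$b2 * 0)
  train_loss <- val_loss <- numeric(cfg$max_epochs)
  best_val <- Inf; best_model <- model; best_epoch <- 0L
  bad <- 0L; epoch <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    g <- ann_loss_grad(model, xt, yt)
    if (!is.finite(g$loss)) {
      stop(lesiontex_error("diverged_training",
                           sprintf("non-finite training loss at epoch %d", epoch),
                           epoch = epoch))
    }
    train_loss[epoch] <- g$loss
    for (nm in c("w1", "b1", "w2", "b2")) {
      vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g[[paste0("d", nm)]]
      model[[nm]] <- model[[nm]] + vel[[nm]]
    }
    vl <- ann_loss_grad(model, xv, yv, want_grad = FALSE)$loss
    if (!is.finite(vl)) {
      stop(lesiontex_error("diverged_training",
                           sprintf("non-finite validation loss at epoch %d", epoch),
                           epoch = epoch))
    }
    val_loss[epoch] <- vl
    if (vl < best_val) {
      best_val <- vl
      best_model <- model
      best_epoch <- epoch
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > cfg$patience) break
    }
  }
  ran <- seq_len(epoch)
  history <- tibble::tibble(epoch = ran,
                            train_loss = train_loss[ran],
                            val_loss = val_loss[ran])
  structure(list(model = best_model, history = history,
                 best_epoch = best_epoch, best_val_loss = best_val,
                 stopped_epoch = epoch, config = cfg),
            class = "ann_fit")
}

#' Predict class indices
#'
#' Argmax of the softmax output; exact ties resolve to the lowest index.
#'
#' @param model An `ann_model` or `ann_fit`.
#' @param x Feature vector or matrix of feature rows.
#' @return Integer class index (1-based) or vector thereof.
#' @export
ann_predict <- function(model, x) {
  if (inherits(model, "ann_fit")) model <- model$model
  p <- ann_forward(model, x)
  if (is.null(dim(p))) return(which.max(p))
  max.col(p, ties.method = "first")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %d -> %d (sigmoid) -> %d (softmax)\n",
              x$n_in, x$n_hidden, x$n_out))
  invisible(x)
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf("<ann_fit> stopped at epoch %d; best validation loss %.5f at epoch %d\n",
              x$stopped_epoch, x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch loss history of a fitted network
#'
#' @param x An `ann_fit`.
#' @param ... Unused.
#' @return A tibble with columns `epoch`, `train_loss`, `val_loss`.
#' @method tidy ann_fit
#' @export
tidy.ann_fit <- function(x, ...) x$history

#' One-row summary of a fitted network
#'
#' @param x An `ann_fit`.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, best epoch, best validation loss,
#'   final training loss, parameter count.
#' @method glance ann_fit
#' @export
glance.ann_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    epochs = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    n_parameters = length(m$w1) + length(m$b1) + length(m$w2) + length(m$b2))
}

#' Serialize a model (or fit) to JSON
#'
#' Stores layer sizes, weights, and biases; [load_ann()] restores them.
#'
#' @param model An `ann_model` or `ann_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_ann <- function(model, path) {
  if (inherits(model, "ann_fit")) model <- model$model
  obj <- list(n_in = model$n_in, n_hidden = model$n_hidden, n_out = model$n_out,
              w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2)
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Restore a model saved by [save_ann()]
#'
#' @param path JSON file written by [save_ann()].
#' @return An `ann_model`.
#' @export
load_ann <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, nr, nc) {
    if (is.matrix(m)) m else matrix(m, nr, nc, byrow = TRUE)
  }
  structure(list(
    w1 = as_mat(obj$w1, obj$n_hidden, obj$n_in),
    b1 = as.numeric(obj$b1),
    w2 = as_mat(obj$w2, obj$n_out, obj$n_hidden),
    b2 = as.numeric(obj$b2),
    n_in = as.integer(obj$n_in), n_hidden = as.integer(obj$n_hidden),
    n_out = as.integer(obj$n_out)), class = "ann_model")
}
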