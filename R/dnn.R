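# The pipeline's classifier: a fully connected network with six ReLU hidden
# layers of 100 units each (plus per-unit biases), dropout after every hidden
# layer, and a single sigmoid output unit trained with binary cross-entropy
# under Adam. Implemented directly in R with matrix arithmetic: minibatches
# of at most a few hundred rows through 100x100 layers are well within
# BLAS territory, and owning the code keeps training bit-reproducible from
# one integer seed (initialisation, shuffling, and dropout masks all draw
# from it).

#' Configure the deep neural network
#'
#' @param n_hidden_layers Hidden layer count (default 6).
#' @param units_per_layer Units per hidden layer (default 100).
#' @param dropout_rate Probability of dropping a hidden unit during training,
#'   in `[0, 1)` (default 0.3; 0 disables dropout).
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 128).
#' @param decision_threshold Score cut-off for the hard tumor call (default 0.5).
#' @param seed Integer seed for init, shuffling, and dropout.
#' @return A `dnn_config` list.
#' @export
dnn_config <- function(n_hidden_layers = 6L, units_per_layer = 100L,
                       dropout_rate = 0.3, learning_rate = 1e-3,
                       epochs = 30L, batch_size = 128L,
                       decision_threshold = 0.5, seed = 1L) {
  cfg <- list(
    n_hidden_layers = assert_count(n_hidden_layers, "n_hidden_layers", 1L),
    units_per_layer = assert_count(units_per_layer, "units_per_layer", 1L),
    dropout_rate = dropout_rate,
    learning_rate = learning_rate,
    epochs = assert_count(epochs, "epochs", 1L),
    batch_size = assert_count(batch_size, "batch_size", 1L),
    decision_threshold = decision_threshold,
    seed = as.integer(seed)
  )
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) stop("'dropout_rate' must be in [0, 1)")
  if (cfg$learning_rate <= 0) stop("'learning_rate' must be > 0")
  class(cfg) <- "dnn_config"
  cfg
}

#' Binary cross-entropy loss
#'
#' L(y, yhat) = -y log(yhat) - (1 - y) log(1 - yhat), natural log, with
#' predictions clipped to `[eps, 1 - eps]`. The training cost is the mean of
#' L over samples.
#'
#' @param y True labels in {0, 1}.
#' @param y_hat Predicted probabilities.
#' @param eps Clipping constant (default 1e-7).
#' @return Per-element losses (same length as `y`); use `mean()` for the cost.
#' @export
bce_loss <- function(y, y_hat, eps = 1e-7) {
  y_hat <- pmin(pmax(y_hat, eps), 1 - eps)
  -y * log(y_hat) - (1 - y) * log(1 - y_hat)
}

relu <- function(z) z * (z > 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# He-normal initialisation for ReLU stacks.
init_layers <- function(n_in, config) {
  sizes <- c(n_in, rep(config$units_per_layer, config$n_hidden_layers), 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    list(
      W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
                 nrow = sizes[l]),
      b = rep(0, sizes[l + 1L])
    )
  })
}

add_bias <- function(z, b) sweep(z, 2L, b, "+")

#' Train the deep neural network on a paired dataset
#'
#' @param dataset A [cartesian_pair()] result (or any list with a numeric
#'   `features` matrix and `labels` of `"tumor"`/`"normal"`); both classes
#'   must be present.
#' @param config A [dnn_config()].
#' @return A `dnn_model`: `layers` (weights/biases), `config`, `feature_names`,
#'   and `history` (mean training BCE per epoch, length `epochs`).
#' @export
dnn_train <- function(dataset, config = dnn_config()) {
  stopifnot(inherits(config, "dnn_config"))
  x <- dataset$features
  y <- as.integer(dataset$labels == "tumor")
  if (nrow(x) == 0L) stop("empty training dataset")
  if (length(unique(y)) < 2L) stop("training data contain a single class")
  feature_names <- colnames(x)
  dimnames(x) <- NULL  # keep weight matrices free of propagated dimnames

  with_seed(config$seed, {
    layers <- init_layers(ncol(x), config)
    L <- length(layers)
    adam <- lapply(layers, function(l) list(
      mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0
    ))
    beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
    lr <- config$learning_rate
    p_drop <- config$dropout_rate
    t_step <- 0L
    history <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(nrow(x))
      batch_starts <- seq(1L, nrow(x), by = config$batch_size)
      epoch_loss <- 0
      for (s in batch_starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, nrow(x))]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)

        # forward, keeping pre-activations and dropout masks
        a <- xb
        zs <- vector("list", L); as <- vector("list", L + 1L)
        masks <- vector("list", L - 1L)
        as[[1L]] <- a
        for (l in seq_len(L - 1L)) {
          z <- add_bias(a %*% layers[[l]]$W, layers[[l]]$b)
          a <- relu(z)
          if (p_drop > 0) {
            mask <- matrix(stats::runif(length(a)) >= p_drop, nrow = nrow(a)) / (1 - p_drop)
            a <- a * mask
            masks[[l]] <- mask
          }
          zs[[l]] <- z
          as[[l + 1L]] <- a
        }
        z_out <- add_bias(a %*% layers[[L]]$W, layers[[L]]$b)
        y_hat <- sigmoid(z_out)
        epoch_loss <- epoch_loss + sum(bce_loss(yb, y_hat))

        # backward: d(mean BCE)/dz_out = (yhat - y)/m for sigmoid + BCE
        delta <- (y_hat - yb) / m
        grads <- vector("list", L)
        for (l in rev(seq_len(L))) {
          grads[[l]] <- list(W = crossprod(as[[l]], delta), b = colSums(delta))
          if (l > 1L) {
            delta <- delta %*% t(layers[[l]]$W)
            if (p_drop > 0) delta <- delta * masks[[l - 1L]]
            delta <- delta * (zs[[l - 1L]] > 0)
          }
        }

        t_step <- t_step + 1L
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        for (l in seq_len(L)) {
          adam[[l]]$mW <- beta1 * adam[[l]]$mW + (1 - beta1) * grads[[l]]$W
          adam[[l]]$vW <- beta2 * adam[[l]]$vW + (1 - beta2) * grads[[l]]$W^2
          adam[[l]]$mb <- beta1 * adam[[l]]$mb + (1 - beta1) * grads[[l]]$b
          adam[[l]]$vb <- beta2 * adam[[l]]$vb + (1 - beta2) * grads[[l]]$b^2
          layers[[l]]$W <- layers[[l]]$W -
            lr * (adam[[l]]$mW / corr1) / (sqrt(adam[[l]]$vW / corr2) + adam_eps)
          layers[[l]]$b <- layers[[l]]$b -
            lr * (adam[[l]]$mb / corr1) / (sqrt(adam[[l]]$vb / corr2) + adam_eps)
        }
      }
      history[epoch] <- epoch_loss / nrow(x)
    }

    structure(
      list(layers = layers, config = config,
           feature_names = feature_names, history = history),
      class = "dnn_model"
    )
  })
}

#' Predict tumor probability for paired rows
#'
#' Inference is deterministic: dropout is off and no randomness is consumed.
#'
#' @param model A trained [dnn_train()] model.
#' @param dataset A paired dataset (or list with a `features` matrix) whose
#'   columns match the training features in order.
#' @return Data frame with `score` (strictly in (0, 1)) and `label`
#'   (`"tumor"` when score > the configured decision threshold).
#' @export
dnn_predict <- function(model, dataset) {
  stopifnot(inherits(model, "dnn_model"))
  x <- if (is.matrix(dataset)) dataset else dataset$features
  if (ncol(x) != nrow(model$layers[[1L]]$W)) {
    stop(sprintf("feature length mismatch: model expects %d, got %d",
                 nrow(model$layers[[1L]]$W), ncol(x)))
  }
  a <- x
  L <- length(model$layers)
  for (l in seq_len(L - 1L)) {
    a <- relu(add_bias(a %*% model$layers[[l]]$W, model$layers[[l]]$b))
  }
  score <- as.numeric(sigmoid(add_bias(a %*% model$layers[[L]]$W, model$layers[[L]]$b)))
  eps <- 1e-12
  score <- pmin(pmax(score, eps), 1 - eps)
  data.frame(
    score = score,
    label = ifelse(score > model$config$decision_threshold, "tumor", "normal"),
    stringsAsFactors = FALSE
  )
}

#' Save / load a trained network as a JSON archive
#'
#' Architecture, configuration, and full-precision weights in one plain-text
#' file.
#'
#' @param model A `dnn_model`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `dnn_load()` returns the restored `dnn_model`.
#' @export
dnn_save <- function(model, path) {
  stopifnot(inherits(model, "dnn_model"))
  payload <- list(
    config = unclass(model$config),
    feature_names = model$feature_names,
    history = model$history,
    layers = lapply(model$layers, function(l) {
      list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname dnn_save
#' @export
dnn_load <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(dnn_config, payload$config)
  lw <- payload$layers
  layers <- lapply(seq_along(lw$W), function(l) {
    list(W = matrix(lw$W[[l]], nrow = lw$dim[[l]][1L]), b = lw$b[[l]])
  })
  structure(
    list(layers = layers, config = cfg,
         feature_names = payload$feature_names, history = payload$history),
    class = "dnn_model"
  )
}
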