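# Baseline classifier adapters with a uniform fit/predict-score contract, so
# the evaluation loop can swap the network for a conventional classifier.
# No SVM/KNN/naive-Bayes implementation ships with the available R stack, so
# these are small self-contained versions: an exact K-nearest-neighbour vote
# (K = 5), an RBF-kernel support vector machine trained by kernelised Pegasos
# subgradient descent (degree-3/gamma conventions follow the usual rbf
# default gamma = 1/n_features), and Gaussian naive Bayes. They are intended
# for comparison runs at the cohort sizes this package simulates, not as
# tuned large-scale implementations.

knn_adapter <- function(k = 5L) {
  list(
    name = "knn",
    fit = function(x, y) list(x = x, y = y, k = k),
    predict_score = function(model, newx) {
      d2 <- outer(rowSums(newx^2), rowSums(model$x^2), "+") -
        2 * newx %*% t(model$x)
      apply(d2, 1L, function(row) {
        nn <- order(row)[seq_len(min(model$k, length(row)))]
        mean(model$y[nn])
      })
    }
  )
}

svm_adapter <- function(epochs = 50L, lambda = 0.01, seed = 1L) {
  list(
    name = "svm",
    fit = function(x, y) {
      yy <- ifelse(y == 1, 1, -1)
      gamma <- 1 / ncol(x)
      K <- exp(-gamma * (outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)))
      n <- nrow(x)
      alpha <- numeric(n)
      with_seed(seed, {
        t_step <- 0L
        for (ep in seq_len(epochs)) {
          for (i in sample.int(n)) {
            t_step <- t_step + 1L
            margin <- yy[i] / (lambda * t_step) * sum(alpha * yy * K[, i])
            if (margin < 1) alpha[i] <- alpha[i] + 1
          }
        }
      })
      list(x = x, yy = yy, alpha = alpha, gamma = gamma,
           scale = 1 / (lambda * t_step))
    },
    predict_score = function(model, newx) {
      Kn <- exp(-model$gamma * (outer(rowSums(newx^2), rowSums(model$x^2), "+") -
                                  2 * newx %*% t(model$x)))
      f <- model$scale * as.numeric(Kn %*% (model$alpha * model$yy))
      1 / (1 + exp(-f))  # squash the margin into (0, 1) for thresholding
    }
  )
}

nb_adapter <- function(var_floor = 1e-9) {
  list(
    name = "nb",
    fit = function(x, y) {
      by_class <- lapply(c(0, 1), function(cl) {
        xc <- x[y == cl, , drop = FALSE]
        list(mu = colMeans(xc),
             var = pmax(col_vars(xc), var_floor),
             log_prior = log(nrow(xc) / nrow(x)))
      })
      names(by_class) <- c("neg", "pos")
      by_class
    },
    predict_score = function(model, newx) {
      ll <- function(cl) {
        cl$log_prior + rowSums(
          -0.5 * log(2 * pi * rep(1, nrow(newx)) %o% cl$var) -
            0.5 * sweep(newx, 2L, cl$mu, "-")^2 /
            (rep(1, nrow(newx)) %o% cl$var)
        )
      }
      lp <- ll(model$pos); ln <- ll(model$neg)
      1 / (1 + exp(ln - lp))
    }
  )
}

#' Baseline classifier adapters
#'
#' Returns a uniform adapter — `list(name, fit(x, y), predict_score(model,
#' newx))` with `y` in {0, 1} and scores in (0, 1) — for one of the
#' conventional classifiers used as comparison points: 5-nearest-neighbour,
#' an RBF-kernel SVM, or Gaussian naive Bayes.
#'
#' @param name One of `"knn"`, `"svm"`, `"nb"`.
#' @param ... Passed to the adapter constructor (e.g. `k` for knn).
#' @return An adapter list.
#' @export
baseline_classifier <- function(name = c("knn", "svm", "nb"), ...) {
  name <- match.arg(name)
  switch(name,
    knn = knn_adapter(...),
    svm = svm_adapter(...),
    nb = nb_adapter(...)
  )
}

#' @rdname baseline_classifier
#' @export
baseline_classifier_names <- function() c("knn", "svm", "nb")
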