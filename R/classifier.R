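# Classification of the 9-feature vectors into DS / US1 / US2.
#
# Features are z-scored (scaler fit on training rows only), then classified
# either by a small dense neural network (9 -> 64 -> 128 -> 256 -> 3, ReLU
# hidden layers, softmax output, cross-entropy loss, Adam) or by a linear
# SVM with C = 30 wrapped one-vs-rest around e1071's binary solver.

#' Canonical feature order
#' @export
FEATURE_NAMES <- c("MMG", "MSG", "SMG", "SSG", "minimum_value", "curvature",
                   "mse", "number_of_particles", "superposition_ratio")

#' Dissolution class labels
#' @export
CLASS_LABELS <- c("DS", "US1", "US2")

as_feature_matrix <- function(features) {
  x <- as.matrix(features[, intersect(colnames(features), FEATURE_NAMES),
                          drop = FALSE])
  if (is.null(colnames(x)) || ncol(x) == 0) x <- as.matrix(features)
  storage.mode(x) <- "double"
  x
}

#' Fit a z-score feature scaler
#'
#' Per-feature mean and population standard deviation learned from training
#' rows only; the fitted scaler is reused verbatim for test rows.
#'
#' @param x numeric matrix (rows = samples, >= 2).
#' @return object of class `feature_scaler`.
#' @section Errors: a zero-variance training feature raises an error naming
#'   the offending feature.
#' @export
fit_scaler <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  mu <- colMeans(x)
  sd_ <- sqrt(colMeans(sweep(x, 2, mu)^2))
  if (any(sd_ == 0)) {
    bad <- colnames(x)[sd_ == 0]
    if (is.null(bad)) bad <- which(sd_ == 0)
    stop("fit_scaler: zero-variance feature(s): ", paste(bad, collapse = ", "))
  }
  structure(list(mean = mu, sd = sd_), class = "feature_scaler")
}

#' Apply / invert a fitted scaler
#'
#' @param scaler a `feature_scaler`.
#' @param x numeric matrix.
#' @export
transform_features <- function(scaler, x) {
  sweep(sweep(as.matrix(x), 2, scaler$mean), 2, scaler$sd, "/")
}

#' @rdname transform_features
#' @export
inverse_transform_features <- function(scaler, x) {
  sweep(sweep(as.matrix(x), 2, scaler$sd, "*"), 2, scaler$mean, "+")
}

#' Dense-network configuration
#'
#' @param hidden hidden-layer widths (input 9 and output 3 are fixed by the
#'   feature set and class count).
#' @param learning_rate Adam step size.
#' @param epochs,batch_size training schedule.
#' @param seed RNG seed for initialization and batch shuffling.
#' @export
dnn_config <- function(hidden = c(64, 128, 256), learning_rate = 0.001,
                       epochs = 100, batch_size = 32, seed = 1L) {
  list(hidden = hidden, learning_rate = learning_rate, epochs = epochs,
       batch_size = batch_size, seed = as.integer(seed))
}

#' Linear-SVM configuration
#'
#' @param cost regularization parameter C (> 0).
#' @export
svm_config <- function(cost = 30) {
  stopifnot(cost > 0)
  list(kernel = "linear", cost = cost)
}

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the dense neural network
#'
#' Fully connected 9 -> 64 -> 128 -> 256 -> 3 network, ReLU hidden
#' activations, softmax output, cross-entropy loss, Adam optimizer
#' (beta1 = 0.9, beta2 = 0.999), He-scaled Gaussian initialization.
#' Deterministic given the seed.
#'
#' @param x scaled feature matrix.
#' @param labels factor or character vector over [CLASS_LABELS]; every class
#'   must be present.
#' @param cfg [dnn_config()].
#' @return object of class `solscreen_dnn` with the weight list and the
#'   per-epoch `loss` trajectory.
#' @export
train_dnn <- function(x, labels, cfg = dnn_config()) {
  x <- as.matrix(x)
  labels <- factor(labels, levels = CLASS_LABELS)
  if (any(table(labels) == 0)) {
    stop("train_dnn: every class must appear in the training labels")
  }
  n <- nrow(x)
  sizes <- c(ncol(x), cfg$hidden, length(CLASS_LABELS))
  nl <- length(sizes) - 1
  yi <- as.integer(labels)
  Y <- matrix(0, n, length(CLASS_LABELS))
  Y[cbind(seq_len(n), yi)] <- 1

  params <- with_seed(cfg$seed, {
    lapply(seq_len(nl), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                   sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1]),
           b = rep(0, sizes[l + 1]))
    })
  })
  m_state <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  v_state <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  step <- 0
  losses <- numeric(cfg$epochs)

  order_seeds <- with_seed(cfg$seed + 1L,
                           sample.int(.Machine$integer.max, cfg$epochs))
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(order_seeds[ep], sample.int(n))
    ep_loss <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n)]
      xb <- x[idx, , drop = FALSE]
      yb <- Y[idx, , drop = FALSE]
      nb <- length(idx)
      # forward
      acts <- vector("list", nl + 1)
      acts[[1]] <- xb
      for (l in seq_len(nl)) {
        z <- acts[[l]] %*% params[[l]]$W +
          matrix(params[[l]]$b, nb, sizes[l + 1], byrow = TRUE)
        acts[[l + 1]] <- if (l < nl) relu(z) else z
      }
      probs <- softmax_rows(acts[[nl + 1]])
      ep_loss <- ep_loss - sum(log(pmax(probs[yb == 1], 1e-12)))
      # backward
      delta <- (probs - yb) / nb
      grads <- vector("list", nl)
      for (l in nl:1) {
        grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                           b = colSums(delta))
        if (l > 1) {
          delta <- (delta %*% t(params[[l]]$W)) * (acts[[l]] > 0)
        }
      }
      # adam update
      step <- step + 1
      for (l in seq_len(nl)) {
        for (nm in c("W", "b")) {
          g <- grads[[l]][[nm]]
          m_state[[l]][[nm]] <- b1 * m_state[[l]][[nm]] + (1 - b1) * g
          v_state[[l]][[nm]] <- b2 * v_state[[l]][[nm]] + (1 - b2) * g^2
          mhat <- m_state[[l]][[nm]] / (1 - b1^step)
          vhat <- v_state[[l]][[nm]] / (1 - b2^step)
          params[[l]][[nm]] <- params[[l]][[nm]] -
            lr * mhat / (sqrt(vhat) + eps)
        }
      }
    }
    losses[ep] <- ep_loss / n
  }
  structure(list(params = params, sizes = sizes, loss = losses, config = cfg),
            class = "solscreen_dnn")
}

#' Class probabilities / predictions from a trained network
#'
#' @param object a `solscreen_dnn`.
#' @param x scaled feature matrix.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.solscreen_dnn <- function(object, x, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  nl <- length(object$params)
  a <- x
  for (l in seq_len(nl)) {
    z <- a %*% object$params[[l]]$W +
      matrix(object$params[[l]]$b, nrow(a), ncol(object$params[[l]]$W),
             byrow = TRUE)
    a <- if (l < nl) relu(z) else z
  }
  probs <- softmax_rows(a)
  colnames(probs) <- CLASS_LABELS
  if (type == "prob") return(probs)
  factor(CLASS_LABELS[max.col(probs, ties.method = "first")],
         levels = CLASS_LABELS)
}

#' Train a one-vs-rest linear SVM
#'
#' One binary linear SVM (C = `cfg$cost`) per class via [e1071::svm()];
#' prediction takes the class with the largest decision value. The convex
#' problem makes training deterministic.
#'
#' @inheritParams train_dnn
#' @param cfg [svm_config()].
#' @return object of class `solscreen_svm`.
#' @importFrom e1071 svm
#' @export
train_svm <- function(x, labels, cfg = svm_config()) {
  x <- as.matrix(x)
  labels <- factor(labels, levels = CLASS_LABELS)
  if (any(table(labels) == 0)) {
    stop("train_svm: every class must appear in the training labels")
  }
  models <- lapply(CLASS_LABELS, function(cls) {
    y <- factor(ifelse(labels == cls, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(x, y, kernel = "linear", cost = cfg$cost, scale = FALSE,
                      type = "C-classification")
    # libsvm orients decision values by the first class seen in the data,
    # not by factor levels; calibrate the sign on the training rows
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")[, 1]
    sgn <- if (mean(dv[y == "pos"]) >= mean(dv[y == "neg"])) 1 else -1
    list(fit = fit, sign = sgn)
  })
  names(models) <- CLASS_LABELS
  structure(list(models = models, config = cfg), class = "solscreen_svm")
}

#' @rdname train_svm
#' @param object a `solscreen_svm`.
#' @param type `"class"` or `"decision"` (per-class decision values).
#' @param ... unused.
#' @export
predict.solscreen_svm <- function(object, x, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  dec <- sapply(CLASS_LABELS, function(cls) {
    m <- object$models[[cls]]
    d <- attr(stats::predict(m$fit, x, decision.values = TRUE),
              "decision.values")
    m$sign * d[, 1]
  })
  dec <- matrix(dec, nrow = nrow(x), dimnames = list(NULL, CLASS_LABELS))
  if (type == "decision") return(dec)
  factor(CLASS_LABELS[max.col(dec, ties.method = "first")],
         levels = CLASS_LABELS)
}

#' Evaluate predictions
#'
#' Accuracy, 3x3 confusion matrix (rows = true, columns = predicted) and
#' one-vs-rest TPR = TP / (TP + FN) and PPV = TP / (TP + FP) per class. A
#' class never predicted has its PPV reported as 0 with `ppv_defined =
#' FALSE`.
#'
#' @param predicted,truth factors/characters over [CLASS_LABELS].
#' @return object of class `eval_report`: `accuracy` (percent), `confusion`,
#'   `tpr`, `ppv`, `ppv_defined`.
#' @export
evaluate_predictions <- function(predicted, truth) {
  predicted <- factor(predicted, levels = CLASS_LABELS)
  truth <- factor(truth, levels = CLASS_LABELS)
  confusion <- table(truth = truth, predicted = predicted)
  tp <- diag(confusion)
  tpr <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), NA_real_)
  col_tot <- colSums(confusion)
  ppv_defined <- col_tot > 0
  ppv <- ifelse(ppv_defined, tp / pmax(col_tot, 1), 0)
  structure(list(accuracy = 100 * mean(predicted == truth),
                 confusion = confusion, tpr = tpr, ppv = ppv,
                 ppv_defined = ppv_defined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> accuracy %.2f%%\n", x$accuracy))
  print(x$confusion)
  cat("TPR:", paste(sprintf("%s %.3f", names(x$tpr), x$tpr), collapse = "  "), "\n")
  cat("PPV:", paste(sprintf("%s %.3f", names(x$ppv), x$ppv), collapse = "  "), "\n")
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class (fold sizes differ by at most one per
#' class); the feature scaler is re-fit inside each training fold so no test
#' information leaks into normalization.
#'
#' @param features unscaled feature matrix.
#' @param labels class labels.
#' @param k number of folds (>= 2); every class needs at least `k` samples.
#' @param model `"dnn"` or `"svm"`.
#' @param seed fold-assignment seed (also seeds per-fold network training).
#' @param dnn_cfg,svm_cfg model configurations.
#' @return list with `fold_accuracy`, `mean_accuracy`, `sd_accuracy`
#'   (percent), and `folds` (the fold index of each row).
#' @export
kfold_cv <- function(features, labels, k = 10, model = c("dnn", "svm"),
                     seed = 1L, dnn_cfg = dnn_config(), svm_cfg = svm_config()) {
  model <- match.arg(model)
  x <- as.matrix(features)
  labels <- factor(labels, levels = CLASS_LABELS)
  stopifnot(k >= 2)
  tab <- table(labels)
  if (any(tab > 0 & tab < k)) {
    stop("kfold_cv: every class present needs at least k samples")
  }
  folds <- integer(length(labels))
  folds_assign <- with_seed(seed, {
    for (cls in levels(labels)) {
      idx <- which(labels == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    folds
  })
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds_assign != f
    scaler <- fit_scaler(x[tr, , drop = FALSE])
    xtr <- transform_features(scaler, x[tr, , drop = FALSE])
    xte <- transform_features(scaler, x[!tr, , drop = FALSE])
    fit <- if (model == "dnn") {
      cfg <- dnn_cfg
      cfg$seed <- as.integer(seed + f)
      train_dnn(xtr, labels[tr], cfg)
    } else {
      train_svm(xtr, labels[tr], svm_cfg)
    }
    pred <- predict(fit, xte)
    acc[f] <- 100 * mean(pred == labels[!tr])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       sd_accuracy = stats::sd(acc), folds = folds_assign)
}
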