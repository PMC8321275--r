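# Desk-scale training harness. The model is a per-pixel multinomial
# logistic (softmax) segmenter over a fixed multi-scale smoothing feature
# bank: enough capacity to segment intensity-separable phantoms, small
# enough that any loss in the family can be exercised end to end on a CPU
# in seconds. Gradients flow through the soft losses analytically; the
# optimiser is SGD with momentum and a piecewise-constant learning-rate
# schedule (drop by a fixed factor every drop_period epochs).

box_mean <- function(img, r) {
  if (r == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  pad <- matrix(0, n + 2 * r, m + 2 * r)
  pad[(r + 1):(r + n), (r + 1):(r + m)] <- img
  # replicate edges
  pad[1:r, ] <- pad[rep(r + 1, r), ]
  pad[(r + n + 1):(r + n + r), ] <- pad[rep(r + n, r), ]
  pad[, 1:r] <- pad[, rep(r + 1, r)]
  pad[, (r + m + 1):(r + m + r)] <- pad[, rep(r + m, r)]
  cs <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  cs <- rbind(0, cbind(0, cs))
  w <- 2 * r + 1
  i0 <- 1:n; j0 <- 1:m
  s <- cs[i0 + w, j0 + w, drop = FALSE] - cs[i0, j0 + w, drop = FALSE] -
    cs[i0 + w, j0, drop = FALSE] + cs[i0, j0, drop = FALSE]
  s / w^2
}

pixel_features <- function(img) {
  n <- nrow(img); m <- ncol(img)
  cbind(1,
        as.vector(img),
        as.vector(box_mean(img, 1)),
        as.vector(box_mean(img, 2)),
        as.vector(box_mean(img, 4)),
        as.vector(matrix(rep(seq_len(n) / n - 0.5, m), n, m)),
        as.vector(matrix(rep(seq_len(m) / m - 0.5, each = n), n, m)))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Training configuration for the per-pixel segmenter
#'
#' Defaults mirror the SGDM recipe typical for segmentation networks
#' (initial learning rate 0.005 dropping to 90% every 20 epochs, momentum
#' 0.9), at a desk-scale epoch count.
#'
#' @param loss A [loss_spec()]; any member of the family is trainable
#'   through the same contract.
#' @param epochs Training epochs. Default 50.
#' @param batch_size Images per minibatch. Default 4.
#' @param lr Initial learning rate. Default 0.005.
#' @param drop_period Epochs between learning-rate drops. Default 20.
#' @param drop_factor Multiplicative drop factor. Default 0.9.
#' @param momentum SGDM momentum. Default 0.9.
#' @param seed Integer seed for init and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = loss_spec("crossE"), epochs = 50,
                         batch_size = 4, lr = 0.005, drop_period = 20,
                         drop_factor = 0.9, momentum = 0.9, seed = 1) {
  stopifnot(inherits(loss, "loss_spec"), epochs >= 1, batch_size >= 1,
            lr >= 0, drop_period >= 1, drop_factor > 0, drop_factor <= 1,
            momentum >= 0, momentum < 1)
  structure(list(loss = loss, epochs = epochs, batch_size = batch_size,
                 lr = lr, drop_period = drop_period,
                 drop_factor = drop_factor, momentum = momentum, seed = seed),
            class = "train_config")
}

#' Train the per-pixel segmenter
#'
#' Minimises the configured loss by SGD with momentum. Within a minibatch,
#' per-class counts are pooled over all images before forming the
#' per-class ratios (micro-averaging), which stabilises the terms of small
#' classes. Divergence (non-finite loss) aborts with the epoch index.
#'
#' @param records List of records with fields `image` and `labelmap`
#'   (e.g. from [generate_patient_series()]), the training split.
#' @param config A [train_config()].
#' @return An object of class `seg_model`: list with the weight matrix
#'   `W` (features x classes), `class_set`, `config` and `loss_history`
#'   (one mean loss per epoch).
#' @export
train_segmenter <- function(records, config = train_config()) {
  stopifnot(length(records) >= 1, inherits(config, "train_config"))
  cs <- lm_class_set(records[[1]]$labelmap)
  feats <- lapply(records, function(r) pixel_features(r$image))
  onehots <- lapply(records, function(r) {
    oh <- as_onehot(r$labelmap)
    matrix(oh, nrow = length(r$labelmap), ncol = cs$C)
  })
  Fdim <- ncol(feats[[1]])
  spec <- config$loss
  with_seed(config$seed, {
    W <- matrix(stats::rnorm(Fdim * cs$C, sd = 0.01), Fdim, cs$C)
    V <- matrix(0, Fdim, cs$C)
    history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      lr <- config$lr * config$drop_factor^floor((ep - 1) / config$drop_period)
      ord <- sample(length(records))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (b in batches) {
        X <- do.call(rbind, feats[b])
        Tm <- do.call(rbind, onehots[b])
        S <- softmax_rows(X %*% W)
        s_arr <- array(S, dim = c(nrow(S), 1, cs$C))
        t_arr <- array(Tm, dim = c(nrow(Tm), 1, cs$C))
        attr(s_arr, "class_set") <- cs
        attr(t_arr, "class_set") <- cs
        lv <- seg_loss(s_arr, t_arr, spec, gradient = TRUE)
        if (!is.finite(lv$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        G <- matrix(lv$gradient, nrow = nrow(S), ncol = cs$C)
        dZ <- S * (G - rowSums(S * G))
        gW <- crossprod(X, dZ)
        V <- config$momentum * V - lr * gW
        W <- W + V
        ep_loss <- ep_loss + lv$loss * length(b)
      }
      history[ep] <- ep_loss / length(records)
    }
  })
  structure(list(W = W, class_set = cs, config = config,
                 loss_history = history),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> %s loss, %d epochs, final training loss %.4f\n",
              x$config$loss$family, x$config$epochs,
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict per-pixel class probabilities for an image
#'
#' @param object A trained [train_segmenter()] model.
#' @param image Numeric intensity matrix.
#' @param ... Unused.
#' @return A [prob_map()] of dimensions H x W x C.
#' @export
predict.seg_model <- function(object, image, ...) {
  X <- pixel_features(image)
  S <- softmax_rows(X %*% object$W)
  prob_map(array(S, dim = c(nrow(image), ncol(image), object$class_set$C)),
           object$class_set)
}

#' Evaluate a model (or oracle) on a test set
#'
#' Predicts each record's labelmap by per-pixel argmax, pools per-class
#' confusion counts over the whole test set, and returns the metric suite.
#'
#' @param model A `seg_model`, or a function `image -> labelmap` (e.g. an
#'   oracle returning the groundtruth).
#' @param records Test records with `image` and `labelmap`.
#' @return A `metric_table` of pooled per-class metrics.
#' @export
evaluate_segmenter <- function(model, records) {
  stopifnot(length(records) >= 1)
  cs <- lm_class_set(records[[1]]$labelmap)
  total <- NULL
  for (r in records) {
    pred <- if (inherits(model, "seg_model"))
      argmax_labelmap(predict(model, r$image))
    else model(r$image)
    if (!identical(lm_class_set(pred)$labels, cs$labels))
      stop("prediction class set does not match the test set")
    cc <- per_class_confusion(r$labelmap, pred)
    if (is.null(total)) total <- cc
    else total[c("TP", "FP", "FN", "TN")] <-
        total[c("TP", "FP", "FN", "TN")] + cc[c("TP", "FP", "FN", "TN")]
  }
  attr(total, "pixels") <- sum(total$TP + total$FP + total$FN + total$TN) /
    nrow(total)
  metric_suite(total)
}
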