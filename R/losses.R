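#' Specify a segmentation loss
#'
#' A loss spec identifies a member of the loss family and its parameters:
#'
#' * `crossE` — class-weighted cross entropy, the mean over pixels of
#'   \eqn{-w_c \log s_{true}}.
#' * `iou` — one minus the class-averaged weighted Jaccard index
#'   \eqn{TP_c / (TP_c + \alpha FP_c + \beta FN_c)}; with
#'   \eqn{\alpha = \beta = 1} this is the plain IoU loss, and other
#'   combinations on the constraint \eqn{\alpha + \beta = 2} trade false
#'   positives against false negatives (a Tversky-style index).
#' * `dice` — one minus the class-averaged
#'   \eqn{2 TP_c / (2 TP_c + \alpha FP_c + \beta FN_c)}.
#'
#' Setting `include_background = FALSE` gives the "noBK" variants that
#' average only over foreground classes; for `crossE` the same intent is
#' expressed by a zero background entry in `class_weights`, which keeps the
#' per-pixel probability simplex intact.
#'
#' @param family One of `"crossE"`, `"iou"`, `"dice"`.
#' @param alpha Weight on false positives (iou/dice families).
#' @param beta Weight on false negatives; `alpha + beta` must equal 2.
#' @param include_background Average over all classes (`TRUE`) or exclude
#'   the background class (`FALSE`). Must stay `TRUE` for `crossE`.
#' @param class_weights Optional per-class nonnegative weights (crossE
#'   only), aligned with the class set, e.g. from
#'   [class_balance_weights()].
#' @param eps Smoothing constant added to numerator and denominator of
#'   per-class ratios so that classes absent from a map (or minibatch)
#'   yield a ratio of 1 instead of 0/0. Default `1e-6`.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(family = c("crossE", "iou", "dice"),
                      alpha = 1, beta = 2 - alpha,
                      include_background = TRUE,
                      class_weights = NULL, eps = 1e-6) {
  family <- match.arg(family)
  if (abs(alpha + beta - 2) > 1e-9) stop("alpha + beta must equal 2")
  if (alpha < 0 || beta < 0) stop("alpha and beta must be nonnegative")
  if (eps <= 0) stop("eps must be positive")
  if (!is.null(class_weights)) {
    if (family != "crossE")
      stop("class_weights apply to crossE only; iou/dice are already class-averaged")
    if (any(class_weights < 0)) stop("class weights must be nonnegative")
  }
  if (family == "crossE" && !include_background)
    stop("crossE noBK is expressed by a zero background class weight, ",
         "not by dropping the background from the average")
  structure(list(family = family, alpha = alpha, beta = beta,
                 include_background = include_background,
                 class_weights = class_weights, eps = eps),
            class = "loss_spec")
}

#' @export
print.loss_spec <- function(x, ...) {
  cat("<loss_spec>", x$family,
      if (x$family != "crossE")
        sprintf("(alpha=%g, beta=%g%s)", x$alpha, x$beta,
                if (x$include_background) "" else ", noBK"),
      "\n")
  invisible(x)
}

#' Derive the no-background variant of a loss spec
#'
#' Turns off the background class in the class average, so the loss value
#' becomes independent of pixels that are background in both the
#' groundtruth and the prediction.
#'
#' @param spec A `iou` or `dice` [loss_spec()].
#' @return The spec with `include_background = FALSE`.
#' @export
make_nobk <- function(spec) {
  stopifnot(inherits(spec, "loss_spec"))
  if (spec$family == "crossE")
    stop("for crossE, set the background class weight to 0 instead")
  spec$include_background <- FALSE
  spec
}

#' Inverse-frequency class-balancing weights
#'
#' Computes one weight per class proportional to the inverse of the class's
#' pixel frequency over a set of training labelmaps, normalised so the mean
#' weight is 1. Rare classes get large weights, the dominant background a
#' small one. A class with zero pixels has no defined frequency; its count
#' is smoothed by adding one pixel, with a warning.
#'
#' @param maps A labelmap or list of labelmaps sharing one class set.
#' @return Named numeric vector of weights (names = class ids), mean 1.
#' @examples
#' # two classes at frequencies 95% / 5% -> weights ~ (0.1, 1.9)
#' @export
class_balance_weights <- function(maps) {
  if (inherits(maps, "labelmap")) maps <- list(maps)
  cs <- lm_class_set(maps[[1]])
  counts <- rep(0, cs$C); names(counts) <- cs$labels
  for (m in maps) {
    tab <- table(factor(as.integer(m), levels = cs$labels))
    counts <- counts + as.numeric(tab)
  }
  if (any(counts == 0)) {
    warning("class(es) with zero pixels: ",
            paste(cs$labels[counts == 0], collapse = ", "),
            "; applying add-one smoothing")
    counts <- counts + 1
  }
  w <- sum(counts) / counts      # 1 / frequency
  w <- w / mean(w)
  names(w) <- cs$labels
  w
}

# Resolve pred/gnd into a per-class soft-count representation.
# pred: labelmap (hard) or H x W x C score array (soft).
# gnd: labelmap or one-hot array.
# Returns list(s = score array, t = one-hot array, cs = class_set).
as_score_pair <- function(pred, gnd) {
  cs <- NULL
  if (inherits(gnd, "labelmap")) {
    cs <- lm_class_set(gnd)
    t <- as_onehot(gnd)
  } else if (length(dim(gnd)) == 3L) {
    t <- unclass(gnd)
    cs <- attr(gnd, "class_set")
  } else stop("gnd must be a labelmap or one-hot array")
  if (inherits(pred, "labelmap")) {
    check_same_geometry(pred, if (inherits(gnd, "labelmap")) gnd else pred)
    s <- as_onehot(pred)
    hard <- TRUE
  } else if (length(dim(pred)) == 3L) {
    s <- unclass(pred)
    if (is.null(cs)) cs <- attr(pred, "class_set")
    hard <- FALSE
  } else stop("pred must be a labelmap or an H x W x C score array")
  if (!all(dim(s) == dim(t)))
    stop("prediction and groundtruth shapes disagree: ",
         paste(dim(s), collapse = "x"), " vs ", paste(dim(t), collapse = "x"))
  if (is.null(cs)) stop("no class_set available on either argument")
  list(s = s, t = t, cs = cs, hard = hard)
}

included_planes <- function(cs, include_background) {
  if (include_background) seq_len(cs$C) else which(cs$labels != cs$background)
}

# Tversky-family loss (iou / dice) on a score pair, optionally with the
# analytic gradient with respect to the scores.
tversky_loss_engine <- function(s, t, cs, spec, gradient) {
  two <- if (spec$family == "dice") 2 else 1
  a <- spec$alpha; b <- spec$beta; eps <- spec$eps
  C <- cs$C
  inc <- included_planes(cs, spec$include_background)
  per <- rep(NA_real_, C); names(per) <- cs$labels
  grad <- if (gradient) array(0, dim = dim(s)) else NULL
  for (k in seq_len(C)) {
    sk <- s[, , k]; tk <- t[, , k]
    TP <- sum(sk * tk); FP <- sum(sk * (1 - tk)); FN <- sum((1 - sk) * tk)
    N <- two * TP + eps
    D <- two * TP + a * FP + b * FN + eps
    per[k] <- N / D
    if (gradient && k %in% inc) {
      dN <- two * tk
      dD <- two * tk + a * (1 - tk) - b * tk
      grad[, , k] <- -(dN * D - N * dD) / D^2 / length(inc)
    }
  }
  loss <- 1 - mean(per[inc])
  structure(list(loss = loss, per_class = 1 - per, gradient = grad,
                 spec = spec), class = "loss_value")
}

cross_entropy_engine <- function(s, t, cs, spec, gradient) {
  w <- spec$class_weights
  if (is.null(w)) w <- rep(1, cs$C)
  if (length(w) != cs$C) stop("class_weights length must equal C")
  eps <- spec$eps
  npix <- dim(s)[1] * dim(s)[2]
  wk <- array(rep(w, each = npix), dim = dim(s))
  sc <- pmax(s, eps)
  loss <- sum(wk * t * -log(sc)) / npix
  per <- vapply(seq_len(cs$C), function(k)
    sum(w[k] * t[, , k] * -log(sc[, , k])) / npix, numeric(1))
  names(per) <- cs$labels
  grad <- NULL
  if (gradient) grad <- -wk * t / sc * (s >= eps) / npix
  structure(list(loss = loss, per_class = per, gradient = grad, spec = spec),
            class = "loss_value")
}

#' Evaluate a segmentation loss
#'
#' Uniform entry point used by the training harness: dispatches on the loss
#' family in `spec`. The prediction may be a labelmap (hard form, the
#' evaluation oracle: probabilities are the one-hot encoding) or an
#' H x W x C probability array (soft form, differentiable: per-class
#' probability-weighted counts \eqn{TP_c = \sum s_c t_c},
#' \eqn{FP_c = \sum s_c (1 - t_c)}, \eqn{FN_c = \sum (1 - s_c) t_c}
#' replace the pixel tallies).
#'
#' @param pred Prediction: [labelmap()] or score array (e.g. [prob_map()]).
#' @param gnd Groundtruth: [labelmap()] or one-hot array.
#' @param spec A [loss_spec()].
#' @param gradient Also return the analytic gradient of the loss with
#'   respect to the prediction scores?
#' @return A `loss_value`: list with `loss` (scalar), `per_class`
#'   (per-class loss terms, named by class id), `gradient` (array or
#'   `NULL`), and `spec`.
#' @export
seg_loss <- function(pred, gnd, spec, gradient = FALSE) {
  stopifnot(inherits(spec, "loss_spec"))
  p <- as_score_pair(pred, gnd)
  if (spec$family == "crossE")
    cross_entropy_engine(p$s, p$t, p$cs, spec, gradient)
  else
    tversky_loss_engine(p$s, p$t, p$cs, spec, gradient)
}

#' @export
print.loss_value <- function(x, ...) {
  cat(sprintf("<loss_value> %s loss = %.6f\n", x$spec$family, x$loss))
  invisible(x)
}

#' Class-weighted cross-entropy loss
#'
#' Mean over pixels of \eqn{-w_c \log s_{true}} where \eqn{s_{true}} is the
#' predicted probability of the pixel's true class and \eqn{w_c} an
#' optional per-class weight (inverse-frequency weights counter class
#' imbalance). Scores are clamped below at `eps` before the log, so the
#' loss is finite; it is zero for a perfect one-hot prediction but, unlike
#' the overlap losses, unbounded above for confidently wrong ones.
#'
#' @inheritParams seg_loss
#' @param spec A crossE [loss_spec()].
#' @return A `loss_value`.
#' @export
weighted_cross_entropy <- function(pred, gnd, spec = loss_spec("crossE"),
                                   gradient = FALSE) {
  if (spec$family != "crossE") stop("spec$family must be crossE")
  seg_loss(pred, gnd, spec, gradient)
}

#' Class-averaged IoU (Jaccard) loss
#'
#' One minus the mean over included classes of
#' \eqn{TP_c / (TP_c + FP_c + FN_c)}, i.e. the weighted form with
#' \eqn{\alpha = \beta = 1}.
#'
#' @inheritParams seg_loss
#' @param spec An iou [loss_spec()] with `alpha = beta = 1`.
#' @return A `loss_value` in \[0, 1\].
#' @export
iou_loss <- function(pred, gnd, spec = loss_spec("iou"), gradient = FALSE) {
  if (spec$family != "iou") stop("spec$family must be iou")
  if (spec$alpha != 1 || spec$beta != 1)
    stop("plain iou loss requires alpha = beta = 1; use iouxy_loss otherwise")
  seg_loss(pred, gnd, spec, gradient)
}

#' Class-averaged dice loss
#'
#' One minus the mean over included classes of
#' \eqn{2 TP_c / (2 TP_c + FP_c + FN_c)}. Because the dice coefficient
#' dominates the Jaccard index pointwise (DSC = 2 JI/(JI+1)), the dice
#' loss never exceeds the IoU loss on the same input.
#'
#' @inheritParams seg_loss
#' @param spec A dice [loss_spec()].
#' @return A `loss_value` in \[0, 1\].
#' @export
dice_loss <- function(pred, gnd, spec = loss_spec("dice"), gradient = FALSE) {
  if (spec$family != "dice") stop("spec$family must be dice")
  seg_loss(pred, gnd, spec, gradient)
}

#' False-positive / false-negative weighted IoU loss
#'
#' One minus the mean over included classes of
#' \eqn{TP_c / (TP_c + \alpha FP_c + \beta FN_c)} with
#' \eqn{\alpha + \beta = 2}, \eqn{\alpha, \beta \ge 0}. \eqn{\alpha > 1}
#' penalises false positives (favouring precision), \eqn{\beta > 1}
#' false negatives (favouring recall); \eqn{\alpha = \beta = 1} recovers
#' the plain IoU loss exactly.
#'
#' @inheritParams seg_loss
#' @param alpha Weight on false positives.
#' @param beta Weight on false negatives (`2 - alpha` by default).
#' @param include_background Include the background class in the average?
#' @param eps Smoothing constant; see [loss_spec()].
#' @return A `loss_value` in \[0, 1\].
#' @export
iouxy_loss <- function(pred, gnd, alpha = 1, beta = 2 - alpha,
                       include_background = TRUE, eps = 1e-6,
                       gradient = FALSE) {
  spec <- loss_spec("iou", alpha = alpha, beta = beta,
                    include_background = include_background, eps = eps)
  seg_loss(pred, gnd, spec, gradient)
}
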