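# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: confusion counts by an explicit
# per-pixel loop, loss values recomputed from the printed formulas.

# naive per-pixel double loop: the reference for per_class_confusion
brute_confusion <- function(gnd, seg, labels) {
  out <- data.frame(class = labels, TP = 0L, FP = 0L, FN = 0L, TN = 0L)
  for (k in seq_along(labels)) {
    cl <- labels[k]
    for (i in seq_len(nrow(gnd))) for (j in seq_len(ncol(gnd))) {
      g <- gnd[i, j] == cl; s <- seg[i, j] == cl
      if (g && s) out$TP[k] <- out$TP[k] + 1L
      else if (!g && s) out$FP[k] <- out$FP[k] + 1L
      else if (g && !s) out$FN[k] <- out$FN[k] + 1L
      else out$TN[k] <- out$TN[k] + 1L
    }
  }
  out
}

# hard tversky-family loss straight from counts (formula transcription)
loss_from_counts <- function(counts, family = "iou", alpha = 1, beta = 1,
                             include_bg = TRUE, eps = 1e-6, background = 0) {
  two <- if (family == "dice") 2 else 1
  keep <- if (include_bg) rep(TRUE, nrow(counts)) else counts$class != background
  r <- with(counts[keep, ],
            (two * TP + eps) / (two * TP + alpha * FP + beta * FN + eps))
  1 - mean(r)
}

random_labelmap <- function(n, m, C, cs = class_set(0:(C - 1))) {
  labelmap(matrix(sample(0:(C - 1), n * m, replace = TRUE), n, m), cs)
}

random_prob_array <- function(n, m, C, cs = class_set(0:(C - 1))) {
  z <- array(stats::rnorm(n * m * C), c(n, m, C))
  e <- exp(z)
  s <- e / rep(apply(e, c(1, 2), sum), C)
  attr(s, "class_set") <- cs
  s
}

# central finite-difference gradient of a loss spec at s
fd_gradient_maxerr <- function(s, gnd, spec, h = 1e-5) {
  cs <- attr(s, "class_set")
  lv <- seg_loss(s, gnd, spec, gradient = TRUE)
  maxerr <- 0
  for (i in seq_along(s)) {
    sp <- s; sp[i] <- sp[i] + h
    sm <- s; sm[i] <- sm[i] - h
    attr(sp, "class_set") <- cs; attr(sm, "class_set") <- cs
    fd <- (seg_loss(sp, gnd, spec)$loss - seg_loss(sm, gnd, spec)$loss) / (2 * h)
    maxerr <- max(maxerr, abs(fd - lv$gradient[i]))
  }
  maxerr
}

# intensity threshold classifier: assigns the class whose mean is nearest
threshold_classifier <- function(means, cs) {
  function(image) {
    idx <- apply(abs(outer(as.vector(image), means, `-`)), 1, which.min)
    labelmap(matrix(cs$labels[idx], nrow(image)), cs)
  }
}
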