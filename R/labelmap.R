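#' Define the set of classes of a segmentation problem
#'
#' A class set is the ordered list of integer class ids a labelmap may
#' contain, together with the id reserved for the background. By the usual
#' indexed-image convention the background is class 0, but any member of
#' `labels` may be designated.
#'
#' @param labels Integer vector of distinct class ids (at least 2).
#' @param background Integer id of the background class; must be one of
#'   `labels`. Default `0L`.
#' @return An object of class `class_set` with fields `labels`,
#'   `background` and `C` (the number of classes).
#' @examples
#' cs <- class_set(0:4)
#' cs$C
#' @export
class_set <- function(labels, background = 0L) {
  labels <- as.integer(labels)
  if (anyDuplicated(labels)) stop("class labels must be distinct")
  if (length(labels) < 2L) stop("a class set needs at least 2 classes")
  background <- as.integer(background)
  if (!background %in% labels) stop("background id must be one of the labels")
  structure(list(labels = labels, background = background, C = length(labels)),
            class = "class_set")
}

#' @export
print.class_set <- function(x, ...) {
  cat("<class_set> C =", x$C, "labels:", paste(x$labels, collapse = " "),
      "(background =", x$background, ")\n")
  invisible(x)
}

#' Construct a labelmap
#'
#' A labelmap is an image-shaped integer matrix in which each pixel holds a
#' class id rather than an intensity; groundtruth (GND) and segmentation
#' output (SEG) are both labelmaps.
#'
#' @param values Integer matrix (rows = image height, row-major pixel grid).
#' @param class_set A [class_set()]; inferred from the values (with
#'   background 0) when omitted.
#' @return An integer matrix of class `labelmap` with a `class_set`
#'   attribute.
#' @export
labelmap <- function(values, class_set = NULL) {
  if (!is.matrix(values)) stop("labelmap values must be a matrix")
  storage.mode(values) <- "integer"
  if (is.null(class_set)) {
    labs <- sort(unique(c(0L, as.integer(values))))
    if (length(labs) < 2L) labs <- c(labs, max(labs) + 1L)
    class_set <- class_set(labs, background = 0L)
  }
  bad <- setdiff(unique(as.integer(values)), class_set$labels)
  if (length(bad))
    stop("labelmap contains ids outside its class set: ", paste(bad, collapse = ", "))
  structure(values, class_set = class_set, class = c("labelmap", "matrix", "array"))
}

#' @export
print.labelmap <- function(x, ...) {
  cs <- attr(x, "class_set")
  cat("<labelmap>", nrow(x), "x", ncol(x), "pixels,", cs$C, "classes\n")
  invisible(x)
}

lm_class_set <- function(x) {
  cs <- attr(x, "class_set")
  if (is.null(cs)) stop("not a labelmap: missing class_set")
  cs
}

check_same_geometry <- function(gnd, seg) {
  if (!all(dim(gnd) == dim(seg)))
    stop("labelmaps differ in dimensions: ", paste(dim(gnd), collapse = "x"),
         " vs ", paste(dim(seg), collapse = "x"))
  g <- lm_class_set(gnd); s <- lm_class_set(seg)
  if (!identical(g$labels, s$labels) || g$background != s$background)
    stop("labelmaps have different class sets")
  g
}

#' One-hot encode a labelmap
#'
#' Expands a labelmap into an H x W x C indicator array: plane `k` is 1
#' where the pixel belongs to the k-th class of the class set.
#'
#' @param x A [labelmap()].
#' @return Numeric array `c(H, W, C)` with a `class_set` attribute.
#' @export
as_onehot <- function(x) {
  cs <- lm_class_set(x)
  a <- array(0, dim = c(nrow(x), ncol(x), cs$C))
  for (k in seq_len(cs$C)) a[, , k] <- (unclass(x) == cs$labels[k]) * 1
  attr(a, "class_set") <- cs
  a
}

#' Construct a per-pixel class-probability map
#'
#' Wraps an H x W x C array of per-pixel class scores. Each pixel's scores
#' must be nonnegative and sum to 1 (within `tol`): the array is a
#' discrete probability simplex per pixel, as produced by a softmax output
#' layer.
#'
#' @param scores Numeric array `c(H, W, C)`.
#' @param class_set A [class_set()] with `C` classes, plane `k` scoring
#'   class `labels[k]`.
#' @param tol Tolerance on the per-pixel sum-to-one check.
#' @return The array, validated, of class `prob_map`.
#' @export
prob_map <- function(scores, class_set, tol = 1e-6) {
  if (length(dim(scores)) != 3L) stop("scores must be an H x W x C array")
  if (dim(scores)[3] != class_set$C) stop("third dimension must equal C")
  if (any(scores < 0)) stop("scores must be nonnegative")
  sums <- apply(scores, c(1, 2), sum)
  if (any(abs(sums - 1) > tol)) stop("per-pixel scores must sum to 1")
  structure(scores, class_set = class_set, class = c("prob_map", "array"))
}

#' Collapse a probability map to a labelmap by per-pixel argmax
#'
#' @param p An H x W x C probability (or score) array with a `class_set`
#'   attribute.
#' @return A [labelmap()]. Ties resolve to the earlier class in the set.
#' @export
argmax_labelmap <- function(p) {
  cs <- attr(p, "class_set")
  if (is.null(cs)) stop("probability array lacks a class_set attribute")
  idx <- apply(unclass(p), c(1, 2), which.max)
  labelmap(matrix(cs$labels[idx], nrow = dim(p)[1]), cs)
}
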