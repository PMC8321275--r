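#' Per-class confusion counts between groundtruth and segmentation
#'
#' For each class c the whole labelmap is treated as a one-vs-rest binary
#' problem: TPc counts pixels labelled c in both maps, FNc pixels labelled c
#' in the groundtruth only, FPc pixels labelled c in the segmentation only,
#' and TNc the remainder, so that TPc + FPc + FNc + TNc equals the total
#' pixel count for every class.
#'
#' @param gnd Groundtruth [labelmap()].
#' @param seg Predicted [labelmap()], same dimensions and class set.
#' @return A data frame of class `confusion_counts` with one row per class
#'   (columns `class`, `TP`, `FP`, `FN`, `TN`) and attributes `pixels`
#'   (total pixel count) and `class_set`.
#' @export
per_class_confusion <- function(gnd, seg) {
  cs <- check_same_geometry(gnd, seg)
  n <- length(gnd)
  g <- as.integer(gnd); s <- as.integer(seg)
  tab <- table(factor(g, levels = cs$labels), factor(s, levels = cs$labels))
  tp <- as.integer(diag(tab))
  fn <- as.integer(rowSums(tab)) - tp   # gnd = c, seg != c
  fp <- as.integer(colSums(tab)) - tp   # gnd != c, seg = c
  tn <- n - tp - fp - fn
  out <- data.frame(class = cs$labels, TP = tp, FP = fp, FN = fn, TN = tn)
  structure(out, pixels = n, class_set = cs,
            class = c("confusion_counts", "data.frame"))
}

#' Build a confusion-count table directly from counts
#'
#' Mostly used for testing metric formulas against hand-computed counts.
#'
#' @param class Integer class ids.
#' @param TP,FP,FN,TN Nonnegative integer counts, recycled to `length(class)`.
#' @param background Background class id.
#' @return A `confusion_counts` data frame, as from [per_class_confusion()].
#' @export
confusion_counts <- function(class, TP, FP, FN, TN = NULL) {
  n <- TP + FP + FN + if (is.null(TN)) 0 else TN
  if (length(unique(n)) > 1L)
    stop("per-class totals must agree (TP+FP+FN+TN constant)")
  if (is.null(TN)) TN <- rep(0, length(TP))
  if (any(c(TP, FP, FN, TN) < 0)) stop("counts must be nonnegative")
  out <- data.frame(class = as.integer(class), TP = TP, FP = FP, FN = FN, TN = TN)
  structure(out, pixels = unique(TP + FP + FN + TN),
            class_set = NULL, class = c("confusion_counts", "data.frame"))
}

ratio_or_na <- function(num, den) ifelse(den > 0, num / den, NA_real_)

#' Per-class metric suite from confusion counts
#'
#' Computes, for every class, accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity
#' (recall) TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), false
#' positive rate FP/(FP+TN), IoU (Jaccard index) TP/(TP+FP+FN) and dice
#' 2TP/(2TP+FP+FN). A metric whose denominator is zero is undefined and
#' reported as `NA`, never coerced to 0 or 1: an absent class has no
#' meaningful overlap ratio, and silently scoring it would bias class
#' averages.
#'
#' @param counts A `confusion_counts` table from [per_class_confusion()].
#' @return A data frame of class `metric_table` with one row per class and
#'   columns `class`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `FPR`, `iou`, `dice`.
#' @export
metric_suite <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    out <- data.frame(
      class       = class,
      accuracy    = ratio_or_na(TP + TN, TP + TN + FP + FN),
      sensitivity = ratio_or_na(TP, TP + FN),
      specificity = ratio_or_na(TN, TN + FP),
      precision   = ratio_or_na(TP, TP + FP),
      FPR         = ratio_or_na(FP, FP + TN),
      iou         = ratio_or_na(TP, TP + FP + FN),
      dice        = ratio_or_na(2 * TP, 2 * TP + FP + FN))
    structure(out, class_set = attr(counts, "class_set"),
              class = c("metric_table", "data.frame"))
  })
}

#' Convert a Jaccard index to the dice coefficient
#'
#' The two overlap measures are linked by DSC = 2 JI / (JI + 1); dice
#' computed this way equals dice computed from the underlying confusion
#' counts for any counts yielding that JI.
#'
#' @param ji Jaccard index (IoU) in \[0, 1\]; vectorised.
#' @return Dice coefficient(s) in \[0, 1\].
#' @examples
#' dice_from_iou(0.5)  # 2/3
#' @export
dice_from_iou <- function(ji) {
  if (any(ji < 0 | ji > 1, na.rm = TRUE)) stop("ji must lie in [0, 1]")
  2 * ji / (ji + 1)
}

#' Average a metric over classes
#'
#' Arithmetic mean of one metric column over classes, optionally excluding
#' the background class (the "noBK" convention). Classes whose value is
#' undefined (`NA`) are excluded from both numerator and denominator.
#'
#' @param table A `metric_table` from [metric_suite()], or any data frame
#'   with a `class` column and metric columns.
#' @param metric Name of the metric column (e.g. `"iou"`).
#' @param include_background Include the background class in the mean?
#' @param background Background class id; taken from the table's class set
#'   when present.
#' @return The mean, a single number.
#' @export
mean_over_classes <- function(table, metric = "iou", include_background = TRUE,
                              background = NULL) {
  if (!metric %in% names(table)) stop("no such metric column: ", metric)
  if (is.null(background)) {
    cs <- attr(table, "class_set")
    background <- if (!is.null(cs)) cs$background else 0L
  }
  v <- table[[metric]]
  keep <- !is.na(v)
  if (!include_background) keep <- keep & table$class != background
  if (!any(keep)) stop("no class has a defined value after exclusion")
  mean(v[keep])
}

#' Append aggregate rows and write a metric table to CSV
#'
#' Adds `mean` and `mean_noBK` rows (class-averaged with and without the
#' background) below the per-class rows and writes the result.
#'
#' @param table A `metric_table`.
#' @param path Output CSV path.
#' @return The augmented data frame, invisibly.
#' @export
write_metric_csv <- function(table, path) {
  metrics <- setdiff(names(table), "class")
  agg <- function(incl) vapply(metrics, function(m) {
    tryCatch(mean_over_classes(table, m, include_background = incl),
             error = function(e) NA_real_)
  }, numeric(1))
  out <- data.frame(class = as.character(table$class), table[metrics],
                    check.names = FALSE)
  out <- rbind(out,
               data.frame(class = "mean", t(agg(TRUE)), check.names = FALSE),
               data.frame(class = "mean_noBK", t(agg(FALSE)), check.names = FALSE))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
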