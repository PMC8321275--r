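# Experimental protocol: patient-wise k-fold cross-validation, uniclass
# problem derivation, alpha sensitivity sweep, and fold-level statistics.

#' Partition patients into cross-validation folds
#'
#' Assigns whole patients to folds (all of a patient's slices travel
#' together), so no patient can appear in both the training and the test
#' side of any split. Fold sizes differ by at most one.
#'
#' @param patients Character or integer vector of distinct patient ids.
#' @param k Number of folds. Default 5 (the 80%/20% protocol).
#' @param seed Integer seed; the random assignment is deterministic in it.
#' @return An object of class `fold_plan`: list with `k`, `seed` and
#'   `assignment` (named integer vector, patient id -> fold index).
#' @export
make_folds <- function(patients, k = 5, seed = 1) {
  patients <- as.character(patients)
  if (anyDuplicated(patients)) stop("patient ids must be distinct")
  n <- length(patients)
  if (n < k) stop("fewer patients (", n, ") than folds (", k, ")")
  with_seed(seed, {
    perm <- sample(patients)
  })
  fold <- rep(seq_len(k), length.out = n)
  assignment <- stats::setNames(fold[match(patients, perm)], patients)
  structure(list(k = k, seed = seed, assignment = assignment),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan>", length(x$assignment), "patients in", x$k, "folds\n")
  print(table(x$assignment))
  invisible(x)
}

#' Test/train patient ids for one split of a fold plan
#'
#' @param plan A [make_folds()] plan.
#' @param fold Fold index in `1:k` used as the test fold.
#' @return List with `test` and `train` patient id vectors (disjoint,
#'   union = all patients).
#' @export
fold_split <- function(plan, fold) {
  stopifnot(inherits(plan, "fold_plan"), fold %in% seq_len(plan$k))
  ids <- names(plan$assignment)
  list(test = ids[plan$assignment == fold],
       train = ids[plan$assignment != fold])
}

#' Reduce a multiclass labelmap to a single-class (uniclass) problem
#'
#' Keeps the target class and relabels every other foreground class as
#' background, producing the binary problem "target vs everything else" —
#' the per-class formulation in which one specialised model is trained per
#' target structure.
#'
#' @param lab A [labelmap()].
#' @param target Foreground class id to keep.
#' @return A [labelmap()] whose class set is \{background, target\}.
#' @export
to_uniclass <- function(lab, target) {
  cs <- lm_class_set(lab)
  target <- as.integer(target)
  if (!target %in% cs$labels) stop("target class not in class set")
  if (target == cs$background) stop("target must not be the background class")
  v <- unclass(lab)
  v[v != target] <- cs$background
  labelmap(v, class_set(c(cs$background, target), background = cs$background))
}

#' Sweep the false-positive weight alpha of the weighted IoU loss
#'
#' Evaluates a user-supplied callback on the grid
#' \eqn{\alpha \in \{0, step, \ldots, 2\}} with \eqn{\beta = 2 - \alpha}
#' (step 0.25 gives 9 grid points). The callback receives `(alpha, beta)`
#' and returns a score (typically a cross-validated mean IoU under an
#' `iouxy` loss with those weights).
#'
#' @param eval_fn Function of `(alpha, beta)` returning a single number.
#' @param step Grid step; must divide 2 evenly. Default 0.25.
#' @return An object of class `sweep_result`: data frame with columns
#'   `alpha`, `beta`, `value`.
#' @export
alpha_sweep <- function(eval_fn, step = 0.25) {
  if (step <= 0 || abs(2 / step - round(2 / step)) > 1e-9)
    stop("step must divide 2 evenly")
  alphas <- seq(0, 2, by = step)
  values <- vapply(alphas, function(a) {
    v <- tryCatch(eval_fn(a, 2 - a), error = function(e)
      stop("sweep callback failed at alpha = ", a, ": ", conditionMessage(e)))
    as.numeric(v)
  }, numeric(1))
  structure(data.frame(alpha = alphas, beta = 2 - alphas, value = values),
            class = c("sweep_result", "data.frame"))
}

#' Fold-level summary statistics
#'
#' Summarises per-fold scores the way cross-validated segmentation results
#' are reported: arithmetic mean, sample (n-1) standard deviation, a
#' symmetric 90% Student-t confidence interval
#' \eqn{mean \pm t_{0.95, n-1} \, sd / \sqrt{n}}, and — when reference
#' fold scores are supplied — a two-sided two-sample pooled-variance
#' t-test p-value against the reference condition.
#'
#' @param values Numeric vector of per-fold scores (length >= 2).
#' @param reference Optional per-fold scores of a reference condition,
#'   same length.
#' @param conf_level Confidence level of the interval. Default 0.90.
#' @return An object of class `fold_stats`: list with `values`, `mean`,
#'   `sd`, `ci_lower`, `ci_upper`, `p_value` (`NA` without a reference),
#'   `n`.
#' @export
fold_stats <- function(values, reference = NULL, conf_level = 0.90) {
  n <- length(values)
  if (n < 2) stop("need at least 2 folds")
  if (!is.null(reference) && length(reference) != n)
    stop("reference must have the same number of folds")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  p <- NA_real_
  if (!is.null(reference))
    p <- stats::t.test(values, reference, var.equal = TRUE)$p.value
  structure(list(values = values, mean = m, sd = s,
                 ci_lower = m - half, ci_upper = m + half,
                 p_value = p, n = n),
            class = "fold_stats")
}

#' @export
print.fold_stats <- function(x, ...) {
  cat(sprintf("<fold_stats> n=%d mean=%.3f sd=%.3f CI=[%.3f, %.3f]",
              x$n, x$mean, x$sd, x$ci_lower, x$ci_upper))
  if (!is.na(x$p_value)) cat(sprintf(" p=%.2g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Side-by-side per-class comparison of evaluation conditions
#'
#' Aligns the per-class values of one metric across conditions (loss
#' functions, multiclass vs uniclass runs, ...) evaluated on the same
#' data, and appends a class-averaged `mean` row. Conditions evaluated on
#' different fold plans are refused, so score differences are attributable
#' to the condition alone.
#'
#' @param tables Named list of `metric_table`s (one per condition).
#' @param metric Metric column to compare. Default `"iou"`.
#' @param fold_plans Optional named list of the `fold_plan`s the
#'   conditions were evaluated under; all must be identical.
#' @return Data frame with one row per class plus a `mean` row, one column
#'   per condition.
#' @export
comparison_report <- function(tables, metric = "iou", fold_plans = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("conditions must be named")
  if (!is.null(fold_plans)) {
    ref <- fold_plans[[1]]
    same <- vapply(fold_plans, function(p)
      identical(p$assignment, ref$assignment), logical(1))
    if (!all(same)) stop("conditions were evaluated on different fold plans")
  }
  classes <- tables[[1]]$class
  for (tb in tables)
    if (!identical(tb$class, classes)) stop("class sets differ across conditions")
  cols <- lapply(tables, function(tb) {
    c(tb[[metric]], mean_over_classes(tb, metric, include_background = TRUE))
  })
  out <- data.frame(class = c(as.character(classes), "mean"),
                    cols, check.names = FALSE)
  names(out) <- c("class", names(tables))
  out
}
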