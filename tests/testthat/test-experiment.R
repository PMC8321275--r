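test_that("patient-wise folds partition the cohort with balanced sizes", {
  ids <- sprintf("P%03d", 1:40)
  plan <- make_folds(ids, k = 5, seed = 1)
  expect_equal(unname(table(plan$assignment)), rep(8L, 5),
               ignore_attr = TRUE)
  # every split: train/test disjoint, union = all patients
  for (f in 1:5) {
    sp <- fold_split(plan, f)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), ids)
  }
  # union of test folds covers each patient exactly once
  tests <- unlist(lapply(1:5, function(f) fold_split(plan, f)$test))
  expect_setequal(tests, ids)
  expect_equal(anyDuplicated(tests), 0L)

  expect_identical(make_folds(ids, 5, seed = 9)$assignment,
                   make_folds(ids, 5, seed = 9)$assignment)
  expect_false(identical(make_folds(ids, 5, seed = 1)$assignment,
                         make_folds(ids, 5, seed = 2)$assignment))

  single <- make_folds(letters[1:5], k = 5, seed = 3)
  expect_equal(unname(table(single$assignment)), rep(1L, 5),
               ignore_attr = TRUE)
  expect_error(make_folds(letters[1:4], k = 5), "fewer patients")
})

test_that("uniclass derivation keeps the target class and nothing else", {
  g <- labelmap(matrix(c(0L, 1L, 2L, 3L), 4, 4), class_set(0:3))
  u <- to_uniclass(g, 1)
  expect_setequal(unique(as.integer(u)), c(0L, 1L))
  expect_identical(sum(u == 1), sum(g == 1))          # conservation
  expect_true(all(unclass(u)[unclass(g) == 2] == 0))  # relabelled to background
  expect_identical(attr(u, "class_set")$labels, c(0L, 1L))
  expect_error(to_uniclass(g, 0), "background")
  expect_error(to_uniclass(g, 9), "not in class set")

  # one problem per foreground class
  probs <- lapply(setdiff(0:3, 0), function(cl) to_uniclass(g, cl))
  expect_length(probs, 3)

  # evaluation-level consistency: per-class metrics of c are unchanged
  set.seed(2)
  s <- random_labelmap(12, 12, 4)
  g2 <- random_labelmap(12, 12, 4)
  multi <- metric_suite(per_class_confusion(g2, s))
  for (cl in 1:3) {
    uni <- metric_suite(per_class_confusion(to_uniclass(g2, cl),
                                            to_uniclass(s, cl)))
    expect_equal(uni$iou[uni$class == cl], multi$iou[multi$class == cl])
  }
})

test_that("alpha sweep walks the constrained grid", {
  seen <- NULL
  res <- alpha_sweep(function(a, b) { seen <<- rbind(seen, c(a, b)); a - b },
                     step = 0.25)
  expect_equal(nrow(res), 9)
  expect_equal(res$alpha, seq(0, 2, 0.25))
  expect_equal(res$beta, 2 - res$alpha)
  expect_true(all(diff(res$alpha) > 0))

  coarse <- alpha_sweep(function(a, b) a, step = 1)
  expect_equal(coarse$alpha, c(0, 1, 2))

  # the alpha = 1 entry is the plain IoU condition, bit-identically
  set.seed(5)
  g <- random_labelmap(10, 10, 3); s <- random_labelmap(10, 10, 3)
  res <- alpha_sweep(function(a, b) iouxy_loss(s, g, alpha = a, beta = b)$loss)
  expect_identical(res$value[res$alpha == 1], iou_loss(s, g)$loss)

  expect_error(alpha_sweep(function(a, b) stop("boom"), step = 1),
               "alpha = 0")
  expect_error(alpha_sweep(function(a, b) a, step = 0.3), "divide 2")
})

test_that("fold statistics reproduce the reference benchmark summaries", {
  tbl <- reference_fold_table()
  byc <- split(tbl$iou, tbl$condition)
  ref <- byc$iou0515

  expect_equal(round(fold_stats(byc$crossE)$mean, 3), 0.835)
  expect_equal(round(fold_stats(byc$dice)$mean, 3), 0.853)
  expect_equal(round(fold_stats(byc$iou11)$mean, 3), 0.860)
  expect_equal(round(fold_stats(ref)$mean, 3), 0.892)

  # p-value against an independent transcription of the pooled t-test
  fs <- fold_stats(byc$crossE, reference = ref)
  n <- 5
  sp2 <- ((n - 1) * var(byc$crossE) + (n - 1) * var(ref)) / (2 * n - 2)
  tstat <- (mean(byc$crossE) - mean(ref)) / sqrt(sp2 * 2 / n)
  p_manual <- 2 * pt(-abs(tstat), df = 2 * n - 2)
  expect_equal(fs$p_value, p_manual, tolerance = 1e-12)
  expect_lt(fs$p_value, 1e-5)   # the difference is significant, df = 8
  expect_gt(fs$p_value, 1e-7)
})

test_that("fold statistics handle degenerate and invalid inputs", {
  fs <- fold_stats(rep(0.5, 5))
  expect_equal(fs$sd, 0)
  expect_equal(fs$ci_lower, 0.5)
  expect_equal(fs$ci_upper, 0.5)
  expect_true(is.na(fs$p_value))

  v <- c(0.7, 0.8, 0.9)
  fs <- fold_stats(v)
  expect_lte(fs$ci_lower, fs$mean)
  expect_gte(fs$ci_upper, fs$mean)
  expect_equal(fs$sd, sd(v))

  expect_error(fold_stats(0.5), "at least 2")
  expect_error(fold_stats(c(0.5, 0.6), reference = c(0.4, 0.5, 0.6)),
               "same number")
})

test_that("comparison reports align conditions per class", {
  g <- generate_phantom(phantom_spec(size = 32, C = 4, bg_frac = 0.8,
                                     seed = 8))$labelmap
  s1 <- perturb(g, perturb_spec(erode_radius = 1, seed = 1))
  t1 <- metric_suite(per_class_confusion(g, s1))
  rep2 <- comparison_report(list(a = t1, b = t1), "iou")
  expect_equal(nrow(rep2), 5)            # 4 classes + mean row
  expect_equal(rep2$a, rep2$b)           # identical conditions, zero difference
  expect_equal(rep2$class[5], "mean")
  expect_equal(rep2$a[5], mean_over_classes(t1, "iou"))

  p1 <- make_folds(letters[1:6], 2, seed = 1)
  p2 <- make_folds(letters[1:6], 2, seed = 2)
  expect_error(comparison_report(list(a = t1, b = t1), "iou",
                                 fold_plans = list(a = p1, b = p2)),
               "different fold plans")
  expect_error(comparison_report(list(t1), "iou"), "named")
})
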