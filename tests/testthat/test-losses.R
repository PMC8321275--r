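make_pair_with_counts <- function() {
  # class 1 in a 3x3 grid: TP=1, FP=1, FN=2 against the groundtruth
  cs <- class_set(0:1)
  gnd <- labelmap(matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE), cs)
  seg <- labelmap(matrix(c(1, 0, 0, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE), cs)
  list(gnd = gnd, seg = seg, cs = cs)
}

test_that("cross entropy evaluates -sum t log s with class weights", {
  cs <- class_set(0:1)
  gnd <- labelmap(matrix(c(0L, 1L), 1, 2), cs)

  # perfect one-hot prediction: loss at the clamp floor
  perfect <- seg_loss(gnd, gnd, loss_spec("crossE"))
  expect_lt(perfect$loss, 1e-9)

  # single pixel with true-class score 0.5 -> -ln(0.5)
  g1 <- labelmap(matrix(1L, 1, 1), cs)
  s <- array(c(0.5, 0.5), c(1, 1, 2)); attr(s, "class_set") <- cs
  expect_equal(weighted_cross_entropy(s, g1)$loss, -log(0.5), tolerance = 1e-9)

  # linear in the class weights
  set.seed(4)
  p <- random_prob_array(4, 4, 2, cs)
  g <- random_labelmap(4, 4, 2, cs)
  l1 <- weighted_cross_entropy(p, g, loss_spec("crossE", class_weights = c(1, 1)))
  l2 <- weighted_cross_entropy(p, g, loss_spec("crossE", class_weights = c(2, 2)))
  expect_equal(l2$loss, 2 * l1$loss, tolerance = 1e-12)
  expect_error(loss_spec("crossE", class_weights = c(-1, 1)), "nonnegative")
})

test_that("hard overlap losses agree with the confusion-count formulas", {
  px <- make_pair_with_counts()
  # single included (foreground) class: IoU term 1/4, dice term 1/2
  liou <- iouxy_loss(px$seg, px$gnd, alpha = 1, include_background = FALSE)
  expect_equal(liou$loss, 1 - 0.25, tolerance = 1e-5)
  ldice <- dice_loss(px$seg, px$gnd, make_nobk(loss_spec("dice")))
  expect_equal(ldice$loss, 1 - 2 / 5, tolerance = 1e-5)  # 1 - 2TP/(2TP+FP+FN)

  # both classes: equals the metric_suite-derived class mean
  cc <- per_class_confusion(px$gnd, px$seg)
  tab <- metric_suite(cc)
  expect_equal(iou_loss(px$seg, px$gnd)$loss,
               1 - mean_over_classes(tab, "iou"), tolerance = 1e-5)
  expect_equal(dice_loss(px$seg, px$gnd)$loss,
               1 - mean_over_classes(tab, "dice"), tolerance = 1e-5)

  # perfect prediction
  expect_lt(iou_loss(px$gnd, px$gnd)$loss, 1e-6)
  expect_lt(dice_loss(px$gnd, px$gnd)$loss, 1e-6)
})

test_that("weighted IoU reduces to plain IoU at alpha = beta = 1 and obeys the examples", {
  set.seed(9)
  g <- random_labelmap(8, 8, 3); s <- random_labelmap(8, 8, 3)
  expect_identical(iouxy_loss(s, g, alpha = 1, beta = 1)$loss,
                   iou_loss(s, g)$loss)
  p <- random_prob_array(8, 8, 3)
  expect_identical(iouxy_loss(p, g, alpha = 1, beta = 1)$loss,
                   iou_loss(p, g)$loss)

  # TP=2, FP=2, FN=0 single class, alpha=0.5: term 2/(2+1) -> loss 1/3
  cs <- class_set(0:1)
  gnd <- labelmap(matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE), cs)
  seg <- labelmap(matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3, byrow = TRUE), cs)
  lv <- iouxy_loss(seg, gnd, alpha = 0.5, include_background = FALSE)
  expect_equal(lv$loss, 1 / 3, tolerance = 1e-5)

  # with FN = 0, the loss is nondecreasing in alpha
  vals <- vapply(seq(0, 2, 0.5), function(a)
    iouxy_loss(seg, gnd, alpha = a, include_background = FALSE)$loss,
    numeric(1))
  expect_true(all(diff(vals) >= 0))

  expect_error(loss_spec("iou", alpha = 1.5, beta = 1.5), "equal 2")
  expect_error(loss_spec("iou", alpha = 2.5, beta = -0.5), "nonnegative")
})

test_that("dice loss never exceeds IoU loss", {
  set.seed(13)
  for (rep in 1:50) {
    C <- sample(2:4, 1)
    g <- random_labelmap(6, 6, C); s <- random_labelmap(6, 6, C)
    expect_lte(dice_loss(s, g)$loss, iou_loss(s, g)$loss + 1e-12)
    p <- random_prob_array(6, 6, C)
    expect_lte(dice_loss(p, g)$loss, iou_loss(p, g)$loss + 1e-12)
  }
})

test_that("soft losses on one-hot probabilities equal the hard forms", {
  set.seed(17)
  for (rep in 1:25) {
    C <- sample(2:5, 1)
    g <- random_labelmap(10, 10, C); s <- random_labelmap(10, 10, C)
    oh <- as_onehot(s)
    expect_equal(seg_loss(oh, g, loss_spec("iou"))$loss,
                 iou_loss(s, g)$loss, tolerance = 1e-12)
    expect_equal(seg_loss(oh, g, loss_spec("dice"))$loss,
                 dice_loss(s, g)$loss, tolerance = 1e-12)
    expect_equal(seg_loss(oh, g, loss_spec("iou", alpha = 0.5))$loss,
                 iouxy_loss(s, g, alpha = 0.5)$loss, tolerance = 1e-12)
  }
})

test_that("noBK variants ignore pixels that are background on both sides", {
  px <- make_pair_with_counts()
  spec <- make_nobk(loss_spec("dice"))
  base <- dice_loss(px$seg, px$gnd, spec)$loss
  # embed the same maps in a larger canvas of correct background
  grow <- function(m) {
    big <- matrix(0L, 6, 6); big[1:3, 1:3] <- unclass(m)
    labelmap(big, attr(m, "class_set"))
  }
  grown <- dice_loss(grow(px$seg), grow(px$gnd), spec)$loss
  expect_equal(grown, base, tolerance = 1e-9)

  # single non-background class: noBK dice equals that class's dice loss
  cc <- per_class_confusion(px$gnd, px$seg)
  dice1 <- with(cc[cc$class == 1, ], 2 * TP / (2 * TP + FP + FN))
  expect_equal(base, 1 - dice1, tolerance = 1e-5)

  expect_error(make_nobk(loss_spec("crossE")), "background class weight")
})

test_that("excluding a strong background raises the loss on imperfect predictions", {
  set.seed(23)
  hits <- 0
  for (rep in 1:40) {
    g <- random_labelmap(8, 8, 3)
    s <- perturb(g, perturb_spec(label_flip_rate = 0.2, seed = rep))
    tab <- metric_suite(per_class_confusion(g, s))
    bg_iou <- tab$iou[tab$class == 0]
    fg_iou <- mean(tab$iou[tab$class != 0], na.rm = TRUE)
    if (is.na(bg_iou) || bg_iou <= fg_iou) next
    hits <- hits + 1
    with_bk <- dice_loss(s, g)$loss
    no_bk <- dice_loss(s, g, make_nobk(loss_spec("dice")))$loss
    expect_gte(no_bk, with_bk - 1e-9)
  }
  expect_gt(hits, 5)  # the regime actually occurred
})

test_that("class balancing weights are inverse-frequency with mean one", {
  cs <- class_set(0:1)
  # 95% / 5% split over 400 pixels
  v <- matrix(0L, 20, 20); v[1:20] <- 1L
  m <- labelmap(v, cs)
  w <- class_balance_weights(m)
  expect_equal(unname(w), c(0.1, 1.9), tolerance = 1e-12)
  expect_equal(mean(w), 1)

  # uniform frequencies -> unit weights
  u <- labelmap(matrix(c(0L, 1L), 10, 10), cs)
  expect_equal(unname(class_balance_weights(u)), c(1, 1))

  # duplicating the dataset leaves weights unchanged
  expect_equal(class_balance_weights(list(m, m)), w)

  # absent class is flagged and smoothed
  allbg <- labelmap(matrix(0L, 5, 5), cs)
  expect_warning(w0 <- class_balance_weights(allbg), "zero pixels")
  expect_true(all(is.finite(w0)))
})

test_that("analytic gradients match central finite differences", {
  set.seed(31)
  cs <- class_set(0:2)
  s <- random_prob_array(4, 4, 3, cs)
  g <- random_labelmap(4, 4, 3, cs)
  specs <- list(crossE = loss_spec("crossE"),
                iou = loss_spec("iou"),
                dice = loss_spec("dice"),
                iouxy0515 = loss_spec("iou", alpha = 0.5, beta = 1.5),
                dice_nobk = make_nobk(loss_spec("dice")))
  for (nm in names(specs))
    expect_lt(fd_gradient_maxerr(s, g, specs[[nm]]), 1e-4)
})

test_that("overlap losses live in [0,1] and vanish only on exact argmax agreement", {
  set.seed(37)
  for (rep in 1:20) {
    g <- random_labelmap(6, 6, 3)
    p <- random_prob_array(6, 6, 3)
    for (spec in list(loss_spec("iou"), loss_spec("dice"))) {
      l <- seg_loss(p, g, spec)$loss
      expect_gte(l, 0); expect_lte(l, 1)
    }
    agree <- identical(unclass(argmax_labelmap(p)), unclass(g))
    l_hard <- iou_loss(argmax_labelmap(p), g)$loss
    if (agree) expect_lt(l_hard, 1e-6) else expect_gt(l_hard, 1e-6)
  }
})
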