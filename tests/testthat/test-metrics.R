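test_that("precision/recall/F1 follow the defining formulas", {
  # the two published per-cell worked examples
  p1 <- prf_from_counts(482, 0, 1233)
  expect_equal(p1$precision, 1)
  expect_equal(round(p1$recall, 2), 0.28)
  expect_equal(round(p1$f1, 2), 0.44)

  p2 <- prf_from_counts(85, 515, 0)
  expect_equal(round(p2$precision, 2), 0.14)
  expect_equal(p2$recall, 1)
  expect_equal(round(p2$f1, 2), 0.25)

  # degenerate convention: all-zero counts give zeros, not NaN
  p0 <- prf_from_counts(0, 0, 0)
  expect_equal(unlist(p0[c("precision", "recall", "f1")]),
               c(precision = 0, recall = 0, f1 = 0))
  expect_error(prf_from_counts(-1, 0, 0), "non-negative")

  # harmonic-mean identity and f1 = 1 <=> precision = recall = 1
  set.seed(2)
  tp <- sample(0:500, 50); fp <- sample(0:200, 50); fn <- sample(0:200, 50)
  p <- prf_from_counts(tp, fp, fn)
  ok <- p$precision + p$recall > 0
  expect_equal(p$f1[ok],
               2 * p$precision[ok] * p$recall[ok] / (p$precision + p$recall)[ok])
  expect_equal(p$f1 == 1, p$precision == 1 & p$recall == 1)
})

test_that("per-cell pixel metrics reproduce the worked examples exactly", {
  cfg <- match_config(iou_threshold = 0.1)

  u <- table4_underestimated()
  res <- match_instances(u$gt, u$pred, cfg)
  pc <- cell_pixel_metrics(u$gt, u$pred, res)
  expect_equal(pc$gt_area, 1715L)
  expect_equal(pc$pred_area, 482L)
  expect_equal(pc$tp, 482L); expect_equal(pc$fp, 0L); expect_equal(pc$fn, 1233L)
  expect_equal(pc$precision, 1)
  expect_equal(round(pc$recall, 2), 0.28)
  expect_equal(round(pc$f1, 2), 0.44)

  o <- table4_overestimated()
  res2 <- match_instances(o$gt, o$pred, cfg)
  pc2 <- cell_pixel_metrics(o$gt, o$pred, res2)
  expect_equal(pc2$tp, 85L); expect_equal(pc2$fp, 515L); expect_equal(pc2$fn, 0L)
  expect_equal(round(pc2$precision, 2), 0.14)
  expect_equal(pc2$recall, 1)
  expect_equal(round(pc2$f1, 2), 0.25)

  # identity gives perfect per-cell scores
  set.seed(9)
  g <- random_rect_map(30, 30, 4)
  ri <- match_instances(g, g)
  pci <- cell_pixel_metrics(g, g, ri)
  expect_true(all(pci$precision == 1 & pci$recall == 1 & pci$f1 == 1))

  # unmatched pair is a contract error
  expect_error(cell_pixel_metrics(g, g, ri, pairs = cbind(1, 99)),
               "not matched")
})

test_that("per-cell conservation holds across perturbed scenes", {
  for (s in 1:6) {
    sc <- small_conifer(seed = s + 10)
    plan <- perturbation_plan(n_erode = 2, erode_px = 1, n_dilate = 1,
                              dilate_px = 1, n_delete = 1, seed = s)
    pp <- perturb_labelmap(sc$labels, plan)
    res <- match_instances(sc$labels, pp$pred)
    pc <- cell_pixel_metrics(sc$labels, pp$pred, res)
    expect_equal(pc$tp + pc$fn, pc$gt_area)
    expect_equal(pc$tp + pc$fp, pc$pred_area)
  }
})

test_that("instance confusion counts the match categories", {
  set.seed(4)
  g <- random_rect_map(40, 40, 10)
  expect_equal(instance_confusion(match_instances(g, g))$f1, 1)

  sc <- small_conifer(seed = 77)
  plan <- perturbation_plan(n_delete = 2, n_spurious = 1, seed = 3)
  pp <- perturb_labelmap(sc$labels, plan)
  res <- match_instances(sc$labels, pp$pred)
  ic <- instance_confusion(res)
  expect_equal(ic$fn, 2L)
  expect_equal(ic$fp, 1L)
  expect_equal(ic$recall, ic$tp / (ic$tp + 2))
})

test_that("aggregation modes differ as hand arithmetic predicts", {
  mk <- function(tp, fp, fn, cells = NULL) {
    list(instance = prf_from_counts(tp, fp, fn),
         per_cell = cells %||%
           data.frame(precision = numeric(0), recall = numeric(0),
                      f1 = numeric(0)))
  }
  one <- mk(9, 1, 1)
  expect_equal(aggregate_summary(list(one), "macro")$f1,
               aggregate_summary(list(one), "micro")$f1)

  two <- list(mk(9, 1, 1), mk(1, 9, 9))
  micro <- aggregate_summary(two, "micro")
  expect_equal(micro$precision, 10 / 20)    # pooled (10, 10, 10)
  expect_equal(micro$recall, 10 / 20)
  macro <- aggregate_summary(two, "macro")
  expect_equal(macro$precision, mean(c(9 / 10, 1 / 10)))

  # with unequal image weights the two aggregations genuinely part ways
  uneq <- list(mk(90, 10, 10), mk(1, 9, 9))
  expect_equal(aggregate_summary(uneq, "micro")$precision, 91 / 110)
  expect_equal(aggregate_summary(uneq, "macro")$precision, mean(c(0.9, 0.1)))
  expect_false(isTRUE(all.equal(aggregate_summary(uneq, "macro")$precision,
                                aggregate_summary(uneq, "micro")$precision)))

  cells <- data.frame(precision = c(1, 0.5), recall = c(1, 1), f1 = c(1, 2 / 3))
  pc <- aggregate_summary(list(mk(1, 0, 0, cells)), "per_cell")
  expect_equal(pc$precision, 0.75)
  expect_error(aggregate_summary(list()), "at least one")
})

test_that("high-accuracy fraction counts cells at the F1 threshold", {
  perfect <- data.frame(f1 = rep(1, 5))
  expect_equal(high_accuracy_fraction(perfect), 1)
  t4 <- data.frame(f1 = c(0.44, 0.25))     # both worked examples fall below
  expect_equal(high_accuracy_fraction(t4), 0)
  mixed <- data.frame(f1 = c(rep(0.95, 7), rep(0.5, 3)))
  expect_equal(high_accuracy_fraction(mixed), 0.7)
  expect_equal(high_accuracy_fraction(mixed, threshold = 0.4), 1)
  expect_error(high_accuracy_fraction(perfect[0, , drop = FALSE]), "empty")
})

test_that("FN size histogram bins missed cells by ground-truth area", {
  sc <- small_conifer(seed = 55)
  res0 <- match_instances(sc$labels, sc$labels)
  h0 <- fn_size_histogram(sc$labels, res0)
  expect_equal(sum(h0$fn_counts), 0L)
  expect_equal(h0$total_fn, 0L)

  plan <- perturbation_plan(n_delete = 4, seed = 8)
  pp <- perturb_labelmap(sc$labels, plan)
  res <- match_instances(sc$labels, pp$pred)
  for (b in c("equal_width", "quantile")) {
    hh <- fn_size_histogram(sc$labels, res, n_bins = 5, binning = b)
    expect_equal(sum(hh$fn_counts), 4L)
    expect_equal(hh$total_fn, 4L)
    expect_true(all(diff(hh$bin_edges) > 0))
    # counts equal a direct per-cell area lookup
    areas <- res$gt_areas[res$fn$gt_id]
    oracle <- table(cut(areas, hh$bin_edges, include.lowest = TRUE))
    expect_equal(hh$fn_counts, as.integer(oracle))
  }

  # all FN below the median in a 2-bin histogram land in bin 1
  gt <- matrix(0L, 30, 60)
  gt[5:6, 5:6] <- 1L; gt[5:6, 10:11] <- 2L          # two 4-px cells
  gt[15:24, 15:24] <- 3L; gt[15:24, 30:39] <- 4L    # two 100-px cells
  pred <- gt; pred[pred %in% c(1L, 2L)] <- 0L        # miss the small ones
  pred <- normalize_labels(pred)
  r <- match_instances(gt, pred)
  h2 <- fn_size_histogram(gt, r, n_bins = 2)
  expect_equal(h2$fn_counts, c(2L, 0L))
})
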