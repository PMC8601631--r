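test_that("intersection table equals the per-pixel double-loop oracle", {
  gt <- matrix(0L, 8, 8); gt[2:4, 2:4] <- 1L
  pred <- matrix(0L, 8, 8); pred[6:7, 6:7] <- 1L
  expect_equal(nrow(intersection_table(gt, pred)), 0L)   # disjoint

  it <- intersection_table(gt, gt)                       # identity
  expect_equal(it$intersection, 9L)
  expect_equal(it$iou, 1)

  set.seed(19)
  for (i in 1:6) {
    g <- random_rect_map(25, 30, 5)
    p <- jittered_prediction(g)
    it <- intersection_table(g, p)
    or <- intersection_oracle(g, p)
    expect_equal(it[c("gt_id", "pred_id", "intersection")], or,
                 ignore_attr = TRUE)
  }
  expect_error(intersection_table(gt, matrix(0L, 4, 4)), "dimensions differ")
})

test_that("incomplete cells are exactly the frame-touching ids", {
  m <- matrix(0L, 10, 10); m[4:6, 4:6] <- 1L
  expect_equal(find_incomplete(m), integer(0))
  m2 <- matrix(0L, 10, 10); m2[4:6, 1:3] <- 1L
  expect_equal(find_incomplete(m2), 1L)

  set.seed(23)
  for (i in 1:6) {
    lab <- random_rect_map(20, 25, 6, margin = 0)
    h <- nrow(lab); w <- ncol(lab)
    oracle <- sort(unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w])))
    oracle <- oracle[oracle > 0]
    expect_equal(find_incomplete(lab), as.integer(oracle))
  }
})

test_that("identity and empty predictions give the trivial results", {
  set.seed(5)
  gt <- random_rect_map(40, 40, 5)
  res <- match_instances(gt, gt)
  expect_equal(nrow(res$matched), 5L)
  expect_equal(nrow(res$fn), 0L)
  expect_equal(nrow(res$fp), 0L)
  expect_true(all(res$matched$iou == 1))

  empty <- matrix(0L, 40, 40)
  res2 <- match_instances(gt, empty)
  expect_equal(nrow(res2$matched), 0L)
  expect_equal(nrow(res2$fn), 5L)
  expect_true(all(res2$fn$reason == "missed"))
})

test_that("split and merge cases are classified per the containment rules", {
  # one 1000-px cell predicted as two disjoint 450-px halves
  gt <- matrix(0L, 60, 60); gt[11:35, 11:50] <- 1L   # 25 x 40 = 1000 px
  pred <- matrix(0L, 60, 60)
  pred[11:35, 11:28] <- 1L                   # 25 x 18 = 450
  pred[11:35, 33:50] <- 2L                   # 25 x 18 = 450
  res <- match_instances(gt, pred)
  expect_equal(nrow(res$matched), 0L)
  expect_equal(res$fn$reason, "disconnected_victim")
  expect_equal(sort(res$fp$pred_id), c(1L, 2L))
  expect_true(all(res$fp$reason == "disconnected_positive"))

  # two adjacent 400-px cells predicted as their joined union
  gt2 <- matrix(0L, 50, 60)
  gt2[11:30, 11:30] <- 1L; gt2[11:30, 33:52] <- 2L   # 2 x 400 px
  pred2 <- matrix(0L, 50, 60)
  pred2[11:30, 11:52] <- 1L                          # union + 2-px bridge band
  res2 <- match_instances(gt2, pred2)
  expect_equal(nrow(res2$matched), 0L)
  expect_equal(res2$fn$reason, c("merged_negative", "merged_negative"))
  expect_equal(res2$fp$reason, "merged_prediction")
})

test_that("border exclusion removes incomplete cells and their predictions", {
  gt <- matrix(0L, 20, 20)
  gt[1:5, 1:5] <- 1L          # clipped by border
  gt[10:14, 10:14] <- 2L      # interior
  pred <- gt                  # prediction identical
  res <- match_instances(gt, pred)
  expect_equal(res$excluded_gt, 1L)
  expect_equal(res$excluded_pred, 1L)
  expect_equal(res$matched$gt_id, 2L)
  expect_equal(nrow(res$fn) + nrow(res$fp), 0L)

  # a prediction majority-inside an excluded cell is excluded, not spurious
  pred2 <- matrix(0L, 20, 20)
  pred2[2:4, 2:4] <- 1L       # interior blob fully inside excluded gt cell 1
  pred2[10:14, 10:14] <- 2L
  res2 <- match_instances(gt, pred2)
  expect_equal(res2$excluded_pred, 1L)
  expect_equal(nrow(res2$fp), 0L)

  res3 <- match_instances(gt, pred, match_config(border_exclusion = FALSE))
  expect_equal(length(res3$excluded_gt), 0L)
  expect_equal(nrow(res3$matched), 2L)
})

test_that("partition identities hold on random perturbed scenes", {
  for (s in 1:10) {
    sc <- small_conifer(seed = s)
    plan <- perturbation_plan(n_delete = 1, n_spurious = 2, n_split = 1,
                              n_merge = 1, n_erode = 1, seed = s + 100)
    pp <- perturb_labelmap(sc$labels, plan)
    res <- match_instances(sc$labels, pp$pred)
    n_alive_gt <- res$n_gt - length(res$excluded_gt)
    n_alive_pred <- res$n_pred - length(res$excluded_pred)
    expect_equal(nrow(res$matched) + nrow(res$fn), n_alive_gt)
    expect_equal(nrow(res$matched) + nrow(res$fp), n_alive_pred)
    # one-to-one
    expect_false(anyDuplicated(res$matched$gt_id) > 0)
    expect_false(anyDuplicated(res$matched$pred_id) > 0)
  }
})

test_that("greedy matching at tau 0.5 equals the exhaustive optimum", {
  set.seed(31)
  cfg <- match_config(border_exclusion = FALSE)
  for (i in 1:30) {
    gt <- random_rect_map(30, 35, sample(3:8, 1))
    pred <- jittered_prediction(gt, keep_prob = 0.8, extra = sample(0:3, 1))
    res <- match_instances(gt, pred, cfg)
    oracle <- exhaustive_match(intersection_table(gt, pred), 0.5)
    got <- res$matched[c("gt_id", "pred_id")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("raising the IoU threshold never increases the match count", {
  set.seed(37)
  for (i in 1:5) {
    gt <- random_rect_map(30, 35, 6)
    pred <- jittered_prediction(gt)
    taus <- c(0.2, 0.35, 0.5, 0.65, 0.8, 0.95)
    counts <- vapply(taus, function(t)
      nrow(match_instances(gt, pred,
                           match_config(iou_threshold = t))$matched), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("swapping roles transposes matches and exchanges categories", {
  # definitional symmetry on a split case
  gt <- matrix(0L, 60, 60); gt[11:35, 11:50] <- 1L
  pred <- matrix(0L, 60, 60)
  pred[11:35, 11:28] <- 1L; pred[11:35, 33:50] <- 2L
  res <- match_instances(gt, pred)
  sw <- swap_roles(res)
  expect_equal(sw$fn$reason, c("merged_negative", "merged_negative"))
  expect_equal(sw$fp$reason, "merged_prediction")

  # swap equals direct reversed evaluation on perturbed scenes
  for (s in 1:8) {
    sc <- small_conifer(seed = s + 40)
    plan <- perturbation_plan(n_delete = 1, n_spurious = 1, n_split = 1,
                              n_merge = 1, seed = s)
    pp <- perturb_labelmap(sc$labels, plan)
    direct <- match_instances(pp$pred, sc$labels)
    sw <- swap_roles(match_instances(sc$labels, pp$pred))
    expect_equal(sw$matched, direct$matched)
    expect_equal(sw$fn, direct$fn)
    expect_equal(sw$fp, direct$fp)
    expect_equal(sw$excluded_gt, direct$excluded_gt)
    expect_equal(sw$excluded_pred, direct$excluded_pred)
  }
})
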