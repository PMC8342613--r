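test_that("confusion counts enumerate the strict-assignment rule", {
  res <- make_results(c(90, 80, 85), c(TRUE, TRUE, FALSE))
  expect_equal(confusion_at_threshold(res, 85, "order"),
               tibble::tibble(TP = 1L, FP = 0L, TN = 1L, FN = 1L),
               ignore_attr = TRUE)
  expect_equal(unlist(confusion_at_threshold(res, 70, "order")[c("FN", "TN")]),
               c(FN = 0L, TN = 0L))                  # t below all similarities
  expect_equal(unlist(confusion_at_threshold(res, 95, "order")[c("TP", "FP")]),
               c(TP = 0L, FP = 0L))                  # t above all similarities
  # results without a hit are excluded
  res$similarity[1] <- NA
  expect_equal(sum(unlist(confusion_at_threshold(res, 85, "order"))), 2L)
})

test_that("counts are conserved at every candidate threshold", {
  withr::local_seed(41)
  res <- random_results(60)
  roc <- roc_curve(res, "order")
  expect_true(all(roc$TP + roc$FP + roc$TN + roc$FN == 60L))
  expect_true(all(diff(roc$TPR) >= 0))  # thresholds descend, rates ascend
  expect_true(all(diff(roc$FPR) >= 0))
})

test_that("AUC matches enumerated cases and the concordance oracle", {
  # perfectly separated classes
  sep <- make_results(c(95, 92, 70), c(TRUE, TRUE, FALSE))
  expect_equal(attr(roc_curve(sep, "order"), "auc"), 1)
  # interleaved: one concordant of two pairs
  mid <- make_results(c(90, 80, 85), c(TRUE, TRUE, FALSE))
  expect_equal(attr(roc_curve(mid, "order"), "auc"), 0.5)
  withr::local_seed(42)
  for (i in 1:5) {
    res <- random_results(40)
    got <- attr(roc_curve(res, "order"), "auc")
    expect_equal(got, oracle_auc(res$similarity, res$correct_order))
  }
})

test_that("AUC agrees with pROC on a random fixture", {
  withr::local_seed(43)
  res <- random_results(80)
  got <- attr(roc_curve(res, "order"), "auc")
  ref <- suppressMessages(
    as.numeric(pROC::auc(pROC::roc(response = res$correct_order,
                                   predictor = res$similarity,
                                   levels = c(FALSE, TRUE), direction = "<"))))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("degenerate single-class results flag the AUC with a reason", {
  res <- make_results(c(90, 80), c(TRUE, TRUE))
  roc <- roc_curve(res, "order")
  expect_true(is.na(attr(roc, "auc")))
  expect_match(attr(roc, "auc_reason"), "no incorrect")
})

test_that("Youden threshold maximises J with ties to the largest threshold", {
  mid <- make_results(c(90, 80, 85), c(TRUE, TRUE, FALSE))
  yt <- youden_threshold(roc_curve(mid, "order"))
  expect_equal(yt$threshold, 85)
  expect_equal(yt$J, 0.5)
  sep <- make_results(c(95, 92, 70), c(TRUE, TRUE, FALSE))
  yt2 <- youden_threshold(roc_curve(sep, "order"))
  expect_equal(yt2$J, 1)
  expect_equal(yt2$threshold, 70)   # the largest incorrect similarity
})

test_that("precision thresholds follow the guarantee rule and its fallback", {
  mid <- make_results(c(90, 80, 85), c(TRUE, TRUE, FALSE))
  expect_equal(precision_threshold(mid, "order", 0), 85)
  allok <- make_results(c(90, 85, 80), c(TRUE, TRUE, TRUE))
  expect_equal(precision_threshold(allok, "order", 0.05), 80)  # min observed
  # 19 correct at 95, 1 incorrect at 96: the boundary FP sits above every
  # correct score, so no threshold below it can guarantee 95% precision and
  # the threshold lands on the FP score itself (strict > excludes it there)
  res <- make_results(c(rep(95, 19), 96), c(rep(TRUE, 19), FALSE))
  expect_equal(precision_threshold(res, "order", 0.05), 96)
  expect_equal(precision_threshold(res, "order", 0), 96)
  # P100 guarantee: zero FP strictly above the returned threshold
  withr::local_seed(44)
  for (i in 1:10) {
    r <- random_results(30)
    t100 <- precision_threshold(r, "order", 0)
    expect_equal(sum(!r$correct_order & r$similarity > t100), 0L)
  }
})

test_that("precision thresholds are ordered P100 >= P99 >= P95", {
  withr::local_seed(45)
  for (i in 1:20) {
    r <- random_results(40)
    t <- vapply(c(0, 0.01, 0.05), function(e) precision_threshold(r, "order", e),
                numeric(1))
    expect_true(t[1] >= t[2] && t[2] >= t[3])
  }
})

test_that("calibrate assembles a consistent report across scopes and ranks", {
  withr::local_seed(46)
  res <- random_results(50)
  res$true_order <- sample(c("O1", "O2"), 50, replace = TRUE)
  rep_all <- calibrate(res, rank = c("order", "family"), scope = "all")
  expect_setequal(unique(rep_all$criterion), c("youden", "P100", "P99", "P95"))
  expect_equal(nrow(rep_all), 8L)
  # single-order input: per-order report equals the global one
  res1 <- res; res1$true_order <- "O1"
  a <- calibrate(res1, rank = "order", scope = "all")
  b <- calibrate(res1, rank = "order", scope = "per_order")
  expect_equal(a[, -(1:2)], b[, -(1:2)], ignore_attr = TRUE)
  # per-order groups cover every true order
  rep_po <- calibrate(res, rank = "order", scope = "per_order")
  expect_setequal(unique(rep_po$group), c("O1", "O2"))
  # assigned fraction decreases as the threshold rises
  rows <- rep_all[rep_all$rank == "order" & rep_all$criterion != "youden", ]
  rows <- rows[order(rows$threshold), ]
  expect_true(all(diff(rows$assigned_fraction) <= 0))
})

test_that("calibrate matches a hand-enumerated fixture", {
  # sims: correct {96, 92, 88}, incorrect {90}; n = 4
  res <- make_results(c(96, 92, 88, 90), c(TRUE, TRUE, TRUE, FALSE))
  rep <- calibrate(res, rank = "order", scope = "all")
  p100 <- rep[rep$criterion == "P100", ]
  # zero-FP guarantee first holds at t = 90 (assigns 96, 92)
  expect_equal(p100$threshold, 90)
  expect_equal(p100$TP, 2L); expect_equal(p100$FP, 0L)
  expect_equal(p100$accuracy, 3 / 4)        # TP=2, TN=1
  expect_equal(p100$assigned_fraction, 0.5)
  p95 <- rep[rep$criterion == "P95", ]
  # precision at t=88: 3/4 = 0.75 < 0.95, so P95 sits at 90 too
  expect_equal(p95$threshold, 90)
  y <- rep[rep$criterion == "youden", ]
  expect_equal(y$threshold, 90)             # TPR 2/3 at FPR 0
  expect_equal(y$J, 2 / 3)
})

test_that("orders with one outcome keep precision thresholds but flag AUC fields", {
  res <- dplyr::bind_rows(
    make_results(c(95, 90, 70), c(TRUE, FALSE, TRUE)),
    make_results(c(93, 91), c(TRUE, TRUE)))
  res$true_order <- c(rep("O1", 3), rep("O2", 2))
  rep <- calibrate(res, rank = "order", scope = "per_order")
  o2 <- rep[rep$group == "O2", ]
  expect_true(all(is.na(o2$auc)))
  expect_true(is.na(o2$threshold[o2$criterion == "youden"]))
  expect_equal(o2$threshold[o2$criterion == "P95"], 91)   # min observed fallback
})
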