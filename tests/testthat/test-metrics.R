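# Region- and patient-level evaluation statistics.

test_that("rates compute exact ratios and mark undefined denominators", {
  r <- rates(confusion_counts(94, 0, 0, 6))
  expect_equal(unname(r["sensitivity"]), 0.94)
  expect_true(is.na(r["specificity"]))   # TN + FP = 0
  r2 <- rates(confusion_counts(0, 5, 0, 3))
  expect_true(is.na(r2["precision"]))    # TP + FP = 0
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("rates agree with recomputation from shuffled prediction tables", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    truth <- rbinom(n, 1, 0.5)
    pred <- rbinom(n, 1, 0.5)
    ord <- sample(n)
    truth_s <- truth[ord]; pred_s <- pred[ord]
    cc <- confusion_counts(sum(pred_s & truth_s), sum(!pred_s & !truth_s),
                           sum(pred_s & !truth_s), sum(!pred_s & truth_s))
    r <- rates(cc)
    # independent recomputation straight from the unshuffled table
    sens <- if (sum(truth) > 0) sum(pred & truth) / sum(truth) else NA_real_
    spec <- if (sum(!truth) > 0) sum(!pred & !truth) / sum(!truth) else NA_real_
    prec <- if (sum(pred) > 0) sum(pred & truth) / sum(pred) else NA_real_
    expect_equal(unname(r), c(sens, spec, prec))
  }
})

test_that("fpavg is the per-patient mean and is cohort additive", {
  expect_equal(fpavg(337, 100), 3.37)
  expect_equal(fpavg(0, 17), 0)
  expect_error(fpavg(3, 0), "at least 1")
  set.seed(4)
  fa <- sample(0:20, 7); fb <- sample(0:20, 5)
  pooled <- fpavg(sum(fa) + sum(fb), 12)
  weighted <- (7 * fpavg(sum(fa), 7) + 5 * fpavg(sum(fb), 5)) / 12
  expect_equal(pooled, weighted)
})

test_that("patient-level accuracy follows the literal and strict rules", {
  p_pos_hit <- patient_predictions("a", TRUE, c(3, 7), c(TRUE, FALSE), S = 130)
  p_neg_clean <- patient_predictions("b", FALSE)
  p_pos_miss <- patient_predictions("c", TRUE, 4, FALSE)
  both <- list(p_pos_hit, p_neg_clean, p_pos_miss)
  expect_equal(ppatient(both, "literal"), 2 / 3)
  expect_equal(ppatient(both, "strict"), 2 / 3)
  # a negative patient with only false positives: the literal indicator
  # (no true CMB predictions) still credits it; strict does not
  p_neg_fp <- patient_predictions("d", FALSE, 1:5, rep(FALSE, 5))
  expect_equal(ppatient(list(p_neg_fp), "literal"), 1)
  expect_equal(ppatient(list(p_neg_fp), "strict"), 0)
  expect_equal(ppatient(list(p_pos_hit, p_neg_clean), "strict"), 1)
  expect_error(ppatient(list(p_pos_hit, p_pos_hit)), "duplicate")
  expect_error(patient_predictions("e", TRUE, 130, TRUE, S = 130), "slice")
})

test_that("literal patient accuracy never falls below strict", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    preds <- lapply(seq_len(n), function(k) {
      m <- rpois(1, 2)
      patient_predictions(paste0("p", k), runif(1) < 0.4,
                          sample(0:9, m, replace = TRUE),
                          runif(m) < 0.5, S = 10)
    })
    expect_gte(ppatient(preds, "literal"), ppatient(preds, "strict"))
  }
})

test_that("mAP handles the perfect, empty and single-overlap cases", {
  gt <- data.frame(image_id = 1L, x1 = 10, y1 = 10, x2 = 20, y2 = 20)
  perfect <- cbind(gt, score = 0.9)
  r <- match_and_map(perfect, gt)
  expect_equal(r$precision, 1); expect_equal(r$recall, 1)
  expect_equal(r$map50, 1); expect_equal(r$map50_95, 1)

  r0 <- match_and_map(perfect[0, ], gt)
  expect_equal(r0$map50, 0); expect_equal(r0$map50_95, 0)

  # one GT, one prediction at IoU = 0.6 (same box shifted 2.5 px:
  # 75/125): AP 1 at thresholds <= 0.6, 0 above
  det <- data.frame(image_id = 1L, x1 = 10, y1 = 12.5, x2 = 20, y2 = 22.5,
                    score = 0.9)
  expect_equal(iou_family(as.matrix(det[, 2:5]), as.matrix(gt[, 2:5])), 0.6,
               tolerance = 1e-9)
  r6 <- match_and_map(det, gt)
  thr <- seq(0.5, 0.95, 0.05)
  expect_equal(unname(r6$ap), as.numeric(thr <= 0.6))
  expect_equal(r6$map50_95, mean(thr <= 0.6))
})

test_that("mAP agrees with the rasterized brute-force oracle", {
  set.seed(21)
  thr <- seq(0.5, 0.95, 0.05)
  for (rep in 1:8) {
    gt <- do.call(rbind, lapply(1:2, function(img) {
      n <- sample(1:5, 1)
      x <- sample(0:40, n); y <- sample(0:40, n)
      data.frame(image_id = img, x1 = x, y1 = y,
                 x2 = x + sample(4:12, n, replace = TRUE),
                 y2 = y + sample(4:12, n, replace = TRUE))
    }))
    det <- do.call(rbind, lapply(seq_len(nrow(gt)), function(k) {
      g <- gt[k, ]
      if (runif(1) < 0.2) return(NULL)
      data.frame(image_id = g$image_id,
                 x1 = g$x1 + sample(-2:2, 1), y1 = g$y1 + sample(-2:2, 1),
                 x2 = g$x2 + sample(-2:2, 1), y2 = g$y2 + sample(-2:2, 1),
                 score = round(runif(1), 3))
    }))
    # a few pure false positives
    fp <- data.frame(image_id = 1L, x1 = 60, y1 = 60, x2 = 70, y2 = 70,
                     score = round(runif(1), 3))
    det <- rbind(det, fp)
    det <- det[det$x2 > det$x1 & det$y2 > det$y1, ]
    r <- match_and_map(det, gt, thr)
    expect_equal(unname(r$ap), oracle_map(det, gt, thr), tolerance = 1e-9)
  }
})

test_that("the aggregated report carries all patient-level quantities", {
  counts <- confusion_counts(8, 20, 4, 2)
  preds <- list(patient_predictions("a", TRUE, 0, TRUE, S = 4),
                patient_predictions("b", FALSE))
  rep <- eval_report(counts, preds)
  expect_equal(rep$sensitivity, 0.8)
  expect_equal(rep$fpavg, 2)
  expect_equal(rep$ppatient_strict, 1)
  expect_s3_class(rep, "eval_report")
  expect_output(print(rep), "FPavg")
})
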