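# Detector construction, inference contracts and training mechanics.
# (The longer smoke-training run lives in the acceptance suite.)

small_cfg <- function(...) detector_config("N", input_size = 96L, seed = 4L, ...)

test_that("construction is deterministic and scales order parameter counts", {
  a <- build_detector(small_cfg())
  b <- build_detector(small_cfg())
  expect_identical(param_checksum(a), param_checksum(b))
  counts <- vapply(c("N", "S", "M", "X6"), function(sc) {
    detector_parameter_count(build_detector(
      detector_config(sc, input_size = 96L, seed = 1L,
                      attention_stages = character())))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
  expect_error(detector_config("Q"), "invalid")
})

test_that("attention insertion adds exactly the blocks' parameter count", {
  with_att <- build_detector(small_cfg())
  without <- build_detector(small_cfg(attention_stages = character()))
  blocks <- Filter(Negate(is.null),
                   list(with_att$att2, with_att$att3, with_att$attn))
  expect_length(blocks, 3)
  delta <- sum(vapply(blocks, function(b)
    saliency_parameter_count(b$cfg), numeric(1)))
  expect_equal(detector_parameter_count(with_att) -
                 detector_parameter_count(without), delta)
})

test_that("NMS is greedy, deterministic and idempotent", {
  boxes <- rbind(c(0, 0, 10, 10), c(1, 1, 11, 11), c(30, 30, 40, 40),
                 c(31, 30, 41, 40), c(100, 100, 108, 108))
  scores <- c(0.9, 0.8, 0.7, 0.75, 0.2)
  ord <- order(-scores)
  keep <- nms_boxes(boxes[ord, ], scores[ord], iou_thr = 0.5)
  kept <- boxes[ord, ][keep, ]
  expect_identical(nrow(kept), 3L)
  keep2 <- nms_boxes(kept, scores[ord][keep], iou_thr = 0.5)
  expect_identical(keep2, seq_len(nrow(kept)))  # idempotent
})

test_that("inference respects thresholds, the candidate cap and determinism", {
  det <- build_detector(small_cfg(score_threshold = 0.25))
  spec <- phantom_spec(slices_per_patient = 3L, image_side = 96L,
                       cmb_diameter = c(4, 20))
  rec <- generate_patient(spec, 12)
  expect_error(detect_patient(det, list()), "empty")
  # a threshold of 1.0 can never be reached by a sigmoid score
  expect_identical(nrow(detect_patient(det, rec$swi, score_threshold = 1.0)), 0L)
  # duplicate slices give identical per-slice detections
  d2 <- detect_patient(det, rec$swi[c(1, 1)], score_threshold = 0.05)
  if (nrow(d2)) {
    a <- d2[d2$slice_index == 0, c("x1", "y1", "x2", "y2", "score")]
    b <- d2[d2$slice_index == 1, c("x1", "y1", "x2", "y2", "score")]
    expect_equal(a[order(a$x1, a$y1), ], b[order(b$x1, b$y1), ],
                 ignore_attr = TRUE)
  }
  # truncation cap: drop the threshold so many raw candidates survive
  d3 <- detect_patient(det, rec$swi, score_threshold = 0, max_candidates = 7)
  expect_lte(nrow(d3), 7L)
  expect_true(!is.unsorted(rev(d3$score)))
  # clipped to image bounds
  expect_true(all(d3$x1 >= 0 & d3$y1 >= 0 & d3$x2 <= 96 & d3$y2 <= 96))
})

test_that("a one-epoch smoke run trains to finite losses, reproducibly", {
  spec <- phantom_spec(slices_per_patient = 8L, image_side = 96L,
                       cmb_diameter = c(4, 20), positive_fraction = 1)
  rec <- generate_patient(spec, 31)
  ds <- lapply(seq_along(rec$swi), function(s)
    list(image = rec$swi[[s]], boxes = rec$gt_boxes[[s]]))
  m1 <- build_detector(small_cfg())
  expect_error(train_detector(m1, list()), "empty")
  r1 <- train_detector(m1, ds, epochs = 1L, seed = 5L, batch_size = 8L)
  expect_true(all(is.finite(r1$trace$loss)))
  expect_true(all(c("obj", "box") %in% names(r1$trace)))
  m2 <- build_detector(small_cfg())
  r2 <- train_detector(m2, ds, epochs = 1L, seed = 5L, batch_size = 8L)
  expect_identical(r1$trace, r2$trace)  # identical seeds, identical traces
})

test_that("decoded boxes mirror under horizontal flip of the score maps", {
  # the decode/NMS geometry is exactly flip-equivariant; verify by
  # flipping the raw head outputs of one forward pass
  det <- build_detector(small_cfg())
  set.seed(8)
  img <- matrix(runif(96 * 96, 0, 255), 96, 96)
  x <- array(rep(img / 255, 3), c(96, 96, 3, 1))
  outs <- forward_detector(det, ag_const(x))
  flip_outs <- lapply(outs, function(o) {
    obj <- ag_value(o$obj); box <- ag_value(o$box)
    W <- dim(obj)[2]
    objf <- obj[, W:1, , , drop = FALSE]
    boxf <- box[, W:1, , , drop = FALSE]
    boxf[, , 1, ] <- -boxf[, , 1, ]     # x offset mirrors
    list(obj = ag_const(objf), box = ag_const(boxf), stride = o$stride)
  })
  d <- decode_detections(outs, 96, 96, 0.2)
  df <- decode_detections(flip_outs, 96, 96, 0.2)
  expect_identical(nrow(d), nrow(df))
  if (nrow(d)) {
    d_m <- d[order(d$y1, d$x1), ]
    df_m <- df[order(df$y1, 96 - df$x2), ]
    expect_equal(df_m$x1, 96 - d_m$x2, tolerance = 1e-9)
    expect_equal(df_m$y1, d_m$y1, tolerance = 1e-9)
    expect_equal(df_m$score, d_m$score, tolerance = 1e-9)
  }
})

test_that("target assignment routes small boxes to the fine level", {
  a <- assign_targets(rbind(c(10, 10, 14, 14), c(40, 40, 70, 70)),
                      96, 96, c(8L, 16L), small_box_px = 16)
  expect_identical(a$level, c(1L, 2L))
  expect_identical(a$i[1], 2L)  # center (12, 12) -> cell 2 at stride 8
  expect_identical(a$j[2], 4L)  # center x = 55 -> cell 4 at stride 16
  # empty ground truth yields an empty assignment
  expect_identical(nrow(assign_targets(NULL, 96, 96, c(8L, 16L), 16)), 0L)
})
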