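# Box geometry: IoU family, NWD similarity/loss, combined regression loss.
# Expected values for the worked small/standard-target configurations were
# computed with the rasterization oracle in helper-oracles.R and frozen.

test_that("IoU and GIoU reproduce the worked small/standard configurations", {
  A <- box(0, 0, 3, 3); B <- box(1, 1, 4, 4)
  D <- box(0, 0, 24, 24); E <- box(1, 0, 25, 24); F <- box(-1, -1, 25, 25)
  expect_equal(round(iou_family(A, B, "iou"), 2), 0.29)
  expect_equal(round(iou_family(A, B, "giou"), 2), 0.16)
  expect_equal(round(iou_family(D, E, "iou"), 2), 0.92)
  expect_equal(round(iou_family(D, F, "iou"), 2), 0.85)
  # frozen oracle values (raster_iou at scale 4)
  expect_equal(iou_family(A, B, "iou"), 4 / 14, tolerance = 1e-12)
  expect_equal(iou_family(D, E, "iou"), 552 / 600, tolerance = 1e-12)
})

test_that("closed-form IoU agrees with the rasterization oracle on a grid", {
  set.seed(42)
  for (i in 1:50) {
    a <- c(0, 0, sample(2:20, 1), sample(2:20, 1))
    shift <- sample(-3:3, 2, replace = TRUE)
    b <- c(shift[1], shift[2], shift[1] + sample(2:20, 1),
           shift[2] + sample(2:20, 1))
    expect_equal(iou_family(matrix(a, 1), matrix(b, 1), "iou"),
                 raster_iou(a, b), tolerance = 1e-9)
  }
})

test_that("identical boxes score 1 for every IoU variant and ~1 for NWD", {
  set.seed(7)
  for (i in 1:10) {
    b <- c(runif(1, -10, 10), runif(1, -10, 10), 0, 0)
    b[3] <- b[1] + runif(1, 1, 30); b[4] <- b[2] + runif(1, 1, 30)
    bb <- matrix(b, 1)
    for (v in c("iou", "giou", "diou", "ciou")) {
      expect_equal(iou_family(bb, bb, v), 1, tolerance = 1e-9)
    }
    s <- nwd_similarity(bb, bb)
    expect_lt(s, 1)
    expect_gte(s, 1 - 1e-3)
  }
})

test_that("IoU-family ordering and symmetry invariants hold", {
  set.seed(11)
  for (i in 1:30) {
    a <- matrix(c(0, 0, runif(1, 2, 30), runif(1, 2, 30)), 1)
    b <- a + matrix(c(runif(2, -5, 5), runif(2, -5, 5)), 1)
    if (b[3] <= b[1]) b[3] <- b[1] + 1
    if (b[4] <= b[2]) b[4] <- b[2] + 1
    iou <- iou_family(a, b, "iou")
    expect_lte(iou_family(a, b, "diou"), iou + 1e-12)
    expect_lte(iou_family(a, b, "ciou"), iou + 1e-12)
    expect_equal(iou_family(a, b, "iou"), iou_family(b, a, "iou"))
    expect_equal(iou_family(a, b, "giou"), iou_family(b, a, "giou"))
    expect_equal(nwd_similarity(a, b), nwd_similarity(b, a))
    # joint integer translation leaves every similarity unchanged
    sh <- matrix(rep(sample(-20:20, 2), 2), 1)
    for (v in c("iou", "giou", "diou", "ciou")) {
      expect_equal(iou_family(a + sh, b + sh, v), iou_family(a, b, v),
                   tolerance = 1e-9)
    }
    expect_equal(nwd_similarity(a + sh, b + sh), nwd_similarity(a, b),
                 tolerance = 1e-9)
  }
})

test_that("GIoU equals IoU when the enclosing box is tight (D-E config)", {
  D <- box(0, 0, 24, 24); E <- box(1, 0, 25, 24)
  expect_equal(iou_family(D, E, "giou"), iou_family(D, E, "iou"),
               tolerance = 1e-12)
})

test_that("NWD similarity matches its closed form and is scale robust", {
  A <- box(0, 0, 3, 3); B <- box(1, 1, 4, 4)
  D <- box(0, 0, 24, 24); E <- box(1, 0, 25, 24)
  expect_equal(nwd_similarity(A, B), exp(-sqrt(2) / 12.8), tolerance = 1e-4)
  expect_equal(nwd_similarity(D, E), exp(-1 / 12.8), tolerance = 1e-4)
  expect_equal(round(nwd_similarity(A, B), 1), 0.9)
  expect_equal(round(nwd_similarity(D, E), 1), 0.9)
  # IoU collapses across the same size change; NWD barely moves
  expect_gt(abs(iou_family(A, B, "iou") - iou_family(D, E, "iou")), 0.5)
  expect_lt(abs(nwd_similarity(A, B) - nwd_similarity(D, E)), 0.05)
})

test_that("the literal center-product reading degenerates on one-axis offsets", {
  D <- box(0, 0, 24, 24); E <- box(1, 0, 25, 24)
  expect_gt(nwd_similarity(D, E, variant = "literal"), 0.999)
  expect_lt(nwd_similarity(D, E), 0.93)
})

test_that("nwd_loss complements similarity and grows with center distance", {
  A <- box(0, 0, 3, 3); B <- box(1, 1, 4, 4)
  expect_equal(nwd_loss(A, B), 1 - nwd_similarity(A, B))
  expect_equal(nwd_loss(A, B), 0.1046, tolerance = 1e-3)
  expect_lt(nwd_loss(A, A), 1e-4)
  prev <- 0
  for (d in c(5, 20, 80, 300)) {
    cur <- nwd_loss(box(0, 0, 3, 3), box(d, 0, d + 3, 3))
    expect_gt(cur, prev)
    prev <- cur
  }
  expect_gt(prev, 0.99 * 1)  # approaches 1
})

test_that("small-target trend: NWD varies less than IoU under a size change", {
  # a 2 px size perturbation of the shifted small box: IoU collapses,
  # NWD moves gently (the exact small-box perturbation behind the
  # published trend cells is underdetermined, so only the contrast is
  # asserted)
  A <- box(0, 0, 3, 3); B <- box(1, 1, 4, 4); C <- box(1, 1, 6, 6)
  d_iou <- iou_family(A, C, "iou") - iou_family(A, B, "iou")
  d_nwd <- nwd_similarity(A, C) - nwd_similarity(A, B)
  expect_lt(abs(d_nwd), abs(d_iou))
  expect_lt(d_iou, -0.15)
  expect_gt(d_nwd, -0.15)
})

test_that("combined loss reduces to its endpoints and is zero on identity", {
  set.seed(3)
  for (i in 1:20) {
    a <- matrix(c(0, 0, runif(1, 2, 30), runif(1, 2, 30)), 1)
    b <- a + matrix(c(runif(2, -4, 4), runif(2, -4, 4)), 1)
    if (b[3] <= b[1]) b[3] <- b[1] + 1
    if (b[4] <= b[2]) b[4] <- b[2] + 1
    expect_equal(combined_regression_loss(a, b, mix = 0),
                 1 - iou_family(a, b, "ciou"), tolerance = 1e-12)
    expect_equal(combined_regression_loss(a, b, mix = 1), nwd_loss(a, b),
                 tolerance = 1e-12)
    for (mix in c(0, 0.5, 1)) {
      expect_lt(combined_regression_loss(a, a, mix = mix), 1e-4)
    }
  }
})

test_that("degenerate boxes and invalid mixing weights are rejected", {
  expect_error(box(0, 0, 0, 3), "degenerate")
  expect_error(iou_family(matrix(c(0, 0, -1, 3), 1), matrix(c(0, 0, 2, 2), 1)),
               "degenerate")
  expect_error(nwd_similarity(matrix(c(0, 0, 2, 2), 1),
                              matrix(c(1, 1, 1, 4), 1)), "degenerate")
  expect_error(combined_regression_loss(box(0, 0, 2, 2), box(0, 0, 2, 2),
                                        mix = 1.5), "mix")
})

test_that("box serialization round-trips through COCO and YOLO forms", {
  b <- matrix(c(10, 20, 16, 28), 1)
  expect_equal(unname(box_to_xywh(b)), matrix(c(10, 20, 6, 8), 1))
  expect_equal(unname(xywh_to_box(box_to_xywh(b))), unname(b))
  y <- box_to_yolo(b, 64, 64)
  expect_equal(as.numeric(y), c(13 / 64, 24 / 64, 6 / 64, 8 / 64))
  expect_equal(unname(yolo_to_box(y, 64, 64)), unname(b), tolerance = 1e-12)
})
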