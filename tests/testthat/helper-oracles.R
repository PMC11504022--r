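# Independent oracles used across tests. These deliberately avoid the
# package's own closed-form code paths.

# IoU by pixel rasterization on an integer grid (half-open boxes), with
# sub-pixel refinement by scaling: exact for integer-coordinate boxes.
raster_iou <- function(a, b, scale = 4L) {
  a <- round(a * scale); b <- round(b * scale)
  x0 <- min(a[1], b[1]); y0 <- min(a[2], b[2])
  x1 <- max(a[3], b[3]); y1 <- max(a[4], b[4])
  W <- x1 - x0; H <- y1 - y0
  grid_a <- matrix(FALSE, H, W)
  grid_b <- matrix(FALSE, H, W)
  fill <- function(g, bx) {
    xs <- (bx[1] - x0 + 1):(bx[3] - x0)
    ys <- (bx[2] - y0 + 1):(bx[4] - y0)
    g[ys, xs] <- TRUE
    g
  }
  grid_a <- fill(grid_a, a); grid_b <- fill(grid_b, b)
  sum(grid_a & grid_b) / sum(grid_a | grid_b)
}

# brute-force greedy matcher + AP on one threshold grid, written
# independently of match_and_map (uses raster_iou, explicit loops)
oracle_map <- function(det, gt, thresholds) {
  det <- det[order(-det$score), , drop = FALSE]
  n_gt <- nrow(gt)
  aps <- numeric(length(thresholds))
  for (ti in seq_along(thresholds)) {
    thr <- thresholds[ti]
    used <- rep(FALSE, n_gt)
    tp <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
      best <- 0; bj <- 0
      for (j in seq_len(n_gt)) {
        if (used[j] || gt$image_id[j] != det$image_id[i]) next
        v <- raster_iou(as.numeric(det[i, c("x1", "y1", "x2", "y2")]),
                        as.numeric(gt[j, c("x1", "y1", "x2", "y2")]))
        if (v > best) { best <- v; bj <- j }
      }
      if (bj > 0 && best >= thr) { tp[i] <- TRUE; used[bj] <- TRUE }
    }
    prec <- cumsum(tp) / seq_along(tp)
    rec <- cumsum(tp) / n_gt
    ap <- 0
    for (r in seq(0, 1, by = 0.01)) {
      pbest <- 0
      for (i in seq_along(rec)) {
        if (rec[i] >= r) pbest <- max(pbest, max(prec[i:length(prec)]))
      }
      ap <- ap + pbest / 101
    }
    aps[ti] <- ap
  }
  aps
}

# finite-difference gradient of a scalar function
num_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# small helper: dataset of per-slice training examples from records
slices_of <- function(recs) {
  out <- list()
  for (r in recs) {
    for (s in seq_along(r$swi)) {
      out[[length(out) + 1L]] <- list(image = r$swi[[s]],
                                      boxes = r$gt_boxes[[s]])
    }
  }
  out
}

# detection recall against ground truth at a given IoU
recall_at <- function(model, examples, iou = 0.3, score = 0.25) {
  tp <- 0; n_gt <- 0
  for (e in examples) {
    n_gt <- n_gt + nrow(e$boxes)
    d <- detect_patient(model, list(e$image), score_threshold = score)
    if (!nrow(d) || !nrow(e$boxes)) next
    used <- logical(nrow(e$boxes))
    for (k in seq_len(nrow(d))) {
      ious <- iou_family(matrix(as.numeric(d[k, c("x1", "y1", "x2", "y2")]),
                                nrow(e$boxes), 4, byrow = TRUE),
                        e$boxes, "iou")
      ious[used] <- -1
      j <- which.max(ious)
      if (ious[j] >= iou) { tp <- tp + 1; used[j] <- TRUE }
    }
  }
  tp / max(n_gt, 1)
}
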