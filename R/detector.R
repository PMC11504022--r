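#' Detector configuration
#'
#' A lightweight anchor-free single-stage detector in the familiar
#' one-stage family: a convolutional backbone with residual
#' (C2f-style) blocks, a two-level feature pyramid neck (strides 8 and
#' 16), and a decoupled head predicting one objectness logit and four
#' box-regression values per cell. Saliency attention blocks
#' ([cmbs_mha()]) can be inserted after the last two backbone stages and
#' after the neck merge; box regression uses the combined CIoU + NWD loss
#' ([combined_regression_loss()]).
#'
#' @param scale One of `"N"`, `"S"`, `"M"`, `"X6"` -- depth/width
#'   multipliers (channel widths roughly 4/8/12/20 x the stage index,
#'   C2f repeats 1/1/2/3).
#' @param input_size Nominal training resolution (must be divisible
#'   by 32; the network itself accepts any size divisible by 16).
#' @param attention_stages Character subset of
#'   `c("backbone2", "backbone3", "neck")`; empty vector disables the
#'   saliency blocks, reducing the model to the plain baseline.
#' @param nms_iou IoU threshold of non-maximum suppression.
#' @param score_threshold Objectness threshold for reporting detections.
#' @param max_candidates_per_patient Global cap on candidates per patient
#'   (default 100).
#' @param nwd_mix NWD mixing weight of the box loss in \[0, 1\].
#' @param small_box_px Boxes with longer side below this are assigned to
#'   the stride-8 level, others to stride 16.
#' @param seed Seed for parameter initialization.
#' @return A list of class `"detector_config"`.
#' @export
detector_config <- function(scale = c("N", "S", "M", "X6"), input_size = 512L,
                            attention_stages = c("backbone2", "backbone3", "neck"),
                            nms_iou = 0.5, score_threshold = 0.25,
                            max_candidates_per_patient = 100L,
                            nwd_mix = 0.5, small_box_px = 16, seed = 1L) {
  if (is.character(scale) && length(scale) >= 1L &&
      !scale[1] %in% c("N", "S", "M", "X6")) {
    stop("invalid detector scale: ", scale[1])
  }
  scale <- match.arg(scale)
  stopifnot(input_size %% 32L == 0L,
            nms_iou > 0, nms_iou < 1,
            score_threshold >= 0, score_threshold <= 1,
            nwd_mix >= 0, nwd_mix <= 1,
            all(attention_stages %in% c("backbone2", "backbone3", "neck")))
  structure(list(scale = scale, input_size = as.integer(input_size),
                 num_classes = 1L, attention_stages = attention_stages,
                 nms_iou = nms_iou, score_threshold = score_threshold,
                 max_candidates_per_patient = as.integer(max_candidates_per_patient),
                 nwd_mix = nwd_mix, small_box_px = small_box_px,
                 seed = as.integer(seed)),
            class = "detector_config")
}

detector_widths <- function(scale) {
  mult <- c(N = 0.25, S = 0.5, M = 0.75, X6 = 1.25)[[scale]]
  w <- pmax(4L, as.integer(round(c(16, 32, 64, 128) * mult / 4) * 4))
  list(widths = w, depth = c(N = 1L, S = 1L, M = 2L, X6 = 3L)[[scale]])
}

c2f_block <- function(w, depth) {
  lapply(seq_len(depth), function(i) {
    list(c1 = layer_conv2d(w, max(w %/% 2L, 2L), k = 3L),
         c2 = layer_conv2d(max(w %/% 2L, 2L), w, k = 3L))
  })
}

forward_c2f <- function(blocks, x) {
  for (b in blocks) {
    h <- forward_conv2d(b$c2, ag_silu(forward_conv2d(b$c1, x)))
    x <- ag_add(x, h)
  }
  x
}

#' Build a detector
#'
#' @param cfg A [detector_config()].
#' @return A model of class `"cmb_detector"`. Construction is fully
#'   deterministic in the configuration (including its seed).
#' @export
build_detector <- function(cfg) {
  stopifnot(inherits(cfg, "detector_config"))
  sw <- detector_widths(cfg$scale)
  w <- sw$widths; depth <- sw$depth
  with_seed(cfg$seed, {
    # token grids capped by the coarsest feature map the nominal input
    # size produces (stride 16)
    kg <- function(stride) {
      g <- max(2L, min(8L, cfg$input_size %/% (2L * stride)))
      g
    }
    att <- function(stage, channels, key_grid) {
      if (stage %in% cfg$attention_stages) {
        cmbs_mha(saliency_attention_config(channels, heads = 4L,
                                           query_grid = min(4L, key_grid),
                                           key_grid = key_grid))
      } else NULL
    }
    model <- list(
      cfg = cfg,
      stem = layer_conv2d(3L, w[1], k = 3L, stride = 2L),
      down1 = layer_conv2d(w[1], w[2], k = 3L, stride = 2L),
      c2f1 = c2f_block(w[2], depth),
      down2 = layer_conv2d(w[2], w[3], k = 3L, stride = 2L),
      c2f2 = c2f_block(w[3], depth),
      att2 = att("backbone2", w[3], kg(8L)),
      down3 = layer_conv2d(w[3], w[4], k = 3L, stride = 2L),
      c2f3 = c2f_block(w[4], depth),
      att3 = att("backbone3", w[4], kg(16L)),
      neck = layer_conv2d(w[4] + w[3], w[3], k = 3L),
      c2fn = c2f_block(w[3], depth),
      attn = att("neck", w[3], kg(8L)),
      head3 = list(stem = layer_conv2d(w[3], w[3], k = 3L),
                   obj = layer_conv2d(w[3], 1L, k = 1L, pad = 0L),
                   box = layer_conv2d(w[3], 4L, k = 1L, pad = 0L)),
      head4 = list(stem = layer_conv2d(w[4], w[4], k = 3L),
                   obj = layer_conv2d(w[4], 1L, k = 1L, pad = 0L),
                   box = layer_conv2d(w[4], 4L, k = 1L, pad = 0L)),
      strides = c(8L, 16L))
    # sparse objectness prior: start heads near "background everywhere"
    model$head3$obj$params$b$value <- -2
    model$head4$obj$params$b$value <- -2
    class(model) <- "cmb_detector"
    model
  })
}

#' @export
print.cmb_detector <- function(x, ...) {
  cat(sprintf("<detector scale %s, %d parameters, attention: %s, NWD mix %.2f>\n",
              x$cfg$scale, detector_parameter_count(x),
              if (length(x$cfg$attention_stages))
                paste(x$cfg$attention_stages, collapse = "+") else "none",
              x$cfg$nwd_mix))
  invisible(x)
}

#' Learnable-parameter count of a detector
#' @param model A `"cmb_detector"`.
#' @return Integer count, deterministic in the configuration.
#' @export
detector_parameter_count <- function(model) n_params(model)

# forward through backbone + neck + heads; x: (H, W, 3, N) in [0, 1]
forward_detector <- function(model, x) {
  h <- ag_silu(forward_conv2d(model$stem, x))
  h <- ag_silu(forward_conv2d(model$down1, h))
  h <- forward_c2f(model$c2f1, h)
  h <- ag_silu(forward_conv2d(model$down2, h))
  h <- forward_c2f(model$c2f2, h)
  if (!is.null(model$att2)) h <- forward_saliency(model$att2, h)
  p3 <- h
  h <- ag_silu(forward_conv2d(model$down3, h))
  h <- forward_c2f(model$c2f3, h)
  if (!is.null(model$att3)) h <- forward_saliency(model$att3, h)
  p4 <- h
  up <- ag_upsample2x(p4)
  n3 <- ag_silu(forward_conv2d(model$neck, ag_cat_channels(up, p3)))
  n3 <- forward_c2f(model$c2fn, n3)
  if (!is.null(model$attn)) n3 <- forward_saliency(model$attn, n3)
  heads <- list(list(feat = n3, head = model$head3, stride = 8L),
                list(feat = p4, head = model$head4, stride = 16L))
  lapply(heads, function(hh) {
    s <- ag_silu(forward_conv2d(hh$head$stem, hh$feat))
    list(obj = forward_conv2d(hh$head$obj, s),
         box = forward_conv2d(hh$head$box, s),
         stride = hh$stride)
  })
}

# concatenate two (H, W, C, N) maps along the channel axis
ag_cat_channels <- function(a, b) {
  da <- dim(ag_value(a)); db <- dim(ag_value(b))
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  am <- ag_reshape(ag_aperm(a, c(3, 1, 2, 4)), c(da[3], prod(da[c(1, 2, 4)])))
  bm <- ag_reshape(ag_aperm(b, c(3, 1, 2, 4)), c(db[3], prod(db[c(1, 2, 4)])))
  m <- ag_rbind(am, bm)
  ag_aperm(ag_reshape(m, c(da[3] + db[3], da[1], da[2], da[4])), c(2, 3, 1, 4))
}

# assign each ground-truth box of one image to (level, cell)
assign_targets <- function(boxes, H, W, strides, small_box_px) {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    return(data.frame(level = integer(), i = integer(), j = integer(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric()))
  }
  m <- as_box_matrix(boxes)
  side <- pmax(m[, 3] - m[, 1], m[, 4] - m[, 2])
  level <- ifelse(side < small_box_px, 1L, 2L)
  st <- strides[level]
  cx <- (m[, 1] + m[, 3]) / 2; cy <- (m[, 2] + m[, 4]) / 2
  j <- pmin(pmax(floor(cx / st), 0), floor(W / st) - 1) + 1L  # column cell
  i <- pmin(pmax(floor(cy / st), 0), floor(H / st) - 1) + 1L  # row cell
  df <- data.frame(level = level, i = as.integer(i), j = as.integer(j),
                   x1 = m[, 1], y1 = m[, 2], x2 = m[, 3], y2 = m[, 4])
  df[!duplicated(df[, c("level", "i", "j")]), , drop = FALSE]
}

# differentiable decode + combined CIoU/NWD loss at positive cells.
# raw: ag (4, P) rows (dx, dy, w, h); cells: data.frame with cell centers
# and stride; gt: (4, P) matrix of target corners.
ag_box_loss_at <- function(raw, cell_cx, cell_cy, stride, gt, mix,
                           cfg = nwd_config()) {
  pcx <- ag_add(ag_mul(ag_tanh(ag_rows(raw, 1L)), stride), matrix(cell_cx, 1))
  pcy <- ag_add(ag_mul(ag_tanh(ag_rows(raw, 2L)), stride), matrix(cell_cy, 1))
  pw <- ag_mul(ag_softplus(ag_rows(raw, 3L)), stride)
  ph <- ag_mul(ag_softplus(ag_rows(raw, 4L)), stride)
  px1 <- ag_sub(pcx, ag_scale(pw, 0.5)); px2 <- ag_add(pcx, ag_scale(pw, 0.5))
  py1 <- ag_sub(pcy, ag_scale(ph, 0.5)); py2 <- ag_add(pcy, ag_scale(ph, 0.5))
  gx1 <- matrix(gt[1, ], 1); gy1 <- matrix(gt[2, ], 1)
  gx2 <- matrix(gt[3, ], 1); gy2 <- matrix(gt[4, ], 1)
  gw <- gx2 - gx1; gh <- gy2 - gy1
  gcx <- (gx1 + gx2) / 2; gcy <- (gy1 + gy2) / 2

  iw <- ag_pmax(ag_sub(ag_pmin(px2, gx2), ag_pmax(px1, gx1)), 0)
  ih <- ag_pmax(ag_sub(ag_pmin(py2, gy2), ag_pmax(py1, gy1)), 0)
  inter <- ag_mul(iw, ih)
  uni <- ag_sub(ag_add(ag_mul(pw, ph), matrix(gw * gh, 1)), inter)
  iou <- ag_div(inter, ag_add(uni, 1e-9))

  ew <- ag_sub(ag_pmax(px2, gx2), ag_pmin(px1, gx1))
  eh <- ag_sub(ag_pmax(py2, gy2), ag_pmin(py1, gy1))
  c2 <- ag_add(ag_add(ag_square(ew), ag_square(eh)), 1e-9)
  rho2 <- ag_add(ag_square(ag_sub(pcx, gcx)), ag_square(ag_sub(pcy, gcy)))
  v <- ag_scale(ag_square(ag_sub(ag_atan(ag_div(pw, ph)),
                                 matrix(atan(gw / gh), 1))), 4 / pi^2)
  v_val <- ag_value(v); iou_val <- ag_value(iou)
  alpha <- ifelse(v_val > 0, v_val / ((1 - iou_val) + v_val), 0)  # detached
  ciou <- ag_sub(ag_sub(iou, ag_div(rho2, c2)), ag_mul(v, matrix(alpha, 1)))

  w2 <- ag_sqrt(ag_add(ag_add(rho2,
          ag_square(ag_scale(ag_sub(pw, matrix(gw, 1)), 0.5))),
          ag_add(ag_square(ag_scale(ag_sub(ph, matrix(gh, 1)), 0.5)),
                 4 * cfg$delta)))
  nwd <- ag_exp(ag_scale(w2, -1 / cfg$C))
  loss <- ag_add(ag_scale(ag_sub(1, ciou), 1 - mix),
                 ag_scale(ag_sub(1, nwd), mix))
  ag_mean(loss)
}

# one training step on a batch; returns list(loss, obj, box, n_pos)
detector_step <- function(model, images, boxes_list, mix, pos_weight = NULL,
                          box_gain = 2) {
  N <- length(images)
  d <- dim(images[[1]])
  x <- array(0, c(d[1], d[2], 3L, N))
  for (n in seq_len(N)) x[, , , n] <- images[[n]]
  outs <- forward_detector(model, ag_const(x))

  obj_losses <- NULL
  box_loss <- NULL
  n_pos_total <- 0L
  for (k in seq_along(outs)) {
    out <- outs[[k]]
    st <- out$stride
    dd <- dim(ag_value(out$obj))        # (Ho, Wo, 1, N)
    Ho <- dd[1]; Wo <- dd[2]
    tgt <- array(0, c(Ho, Wo, 1L, N))
    pos <- list()
    for (n in seq_len(N)) {
      a <- assign_targets(boxes_list[[n]], d[1], d[2], model$strides,
                          model$cfg$small_box_px)
      a <- a[a$level == k, , drop = FALSE]
      if (nrow(a)) {
        tgt[cbind(a$i, a$j, 1L, n)] <- 1
        pos[[length(pos) + 1L]] <- cbind(a$i, a$j, n, a$x1, a$y1, a$x2, a$y2)
      }
    }
    # balance the sparse positives against the sea of background cells;
    # capped so a near-empty batch cannot blow up the effective step
    pw <- pos_weight %||%
      min(150, max(10, 0.25 * sum(tgt == 0) / max(sum(tgt > 0), 1)))
    wts <- ifelse(tgt > 0, pw, 1)
    obj_losses[[length(obj_losses) + 1L]] <-
      ag_bce_logits(out$obj, tgt, weights = wts)
    if (length(pos)) {
      pm <- do.call(rbind, pos)
      P <- nrow(pm)
      n_pos_total <- n_pos_total + P
      # gather raw box predictions at the positive cells: (4, P)
      idx <- matrix(0L, 4L, P)
      for (c in 1:4) {
        idx[c, ] <- pm[, 1] + Ho * (pm[, 2] - 1L) + Ho * Wo * (c - 1L) +
          Ho * Wo * 4L * (pm[, 3] - 1L)
      }
      raw <- ag_index_select(out$box, idx, out_dim = c(4L, P))
      cell_cx <- (pm[, 2] - 0.5) * st
      cell_cy <- (pm[, 1] - 0.5) * st
      bl <- ag_box_loss_at(raw, cell_cx, cell_cy, st,
                           t(pm[, 4:7, drop = FALSE]), mix)
      box_loss <- if (is.null(box_loss)) bl else ag_add(box_loss, bl)
    }
  }
  obj <- ag_scale(ag_add(obj_losses[[1]], obj_losses[[2]]), 0.5)
  total <- if (is.null(box_loss)) obj else
    ag_add(obj, ag_scale(box_loss, box_gain))
  list(total = total, obj = ag_value(obj),
       box = if (is.null(box_loss)) 0 else ag_value(box_loss),
       n_pos = n_pos_total)
}

#' Train a detector on labelled slices
#'
#' Plain Adam training with seeded shuffling. The returned trace reports
#' the box-regression component separately from the objectness component,
#' which is what makes the training-stability comparison between NWD
#' mixing weights observable.
#'
#' @param model A `"cmb_detector"` (modified in place and returned).
#' @param dataset List of training examples, each a list with `image`
#'   (an `H x W` matrix on the 0--255 scale, or `H x W x 3` in \[0, 1\])
#'   and `boxes` (`n x 4` corner matrix; may have zero rows).
#' @param epochs Number of passes over the data (>= 1).
#' @param seed RNG seed; identical seeds give identical loss traces.
#' @param lr,batch_size Optimizer settings.
#' @return List with `model` and `trace` (data frame with per-step
#'   `loss`, `obj`, `box` columns).
#' @export
train_detector <- function(model, dataset, epochs = 10L, seed = 1L,
                           lr = 3e-3, batch_size = 8L) {
  stopifnot(inherits(model, "cmb_detector"), epochs >= 1L)
  if (!length(dataset)) stop("empty training dataset")
  images <- lapply(dataset, function(ex) prep_image(ex$image))
  boxes <- lapply(dataset, function(ex) ex$boxes)
  params <- collect_params(model)
  opt <- adam_init(params, lr = lr)
  trace <- list()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(dataset))
      for (b0 in seq(1, length(ord), by = batch_size)) {
        sel <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        ag_zero_grads(params)
        st <- detector_step(model, images[sel], boxes[sel], model$cfg$nwd_mix)
        ag_backward(st$total)
        clip_gradients(params)
        opt <- adam_step(opt)
        trace[[length(trace) + 1L]] <- data.frame(
          epoch = ep, loss = ag_value(st$total), obj = st$obj, box = st$box,
          n_pos = st$n_pos)
      }
    }
  })
  list(model = model, trace = do.call(rbind, trace))
}

# accept H x W 0-255 matrix or H x W x 3 [0,1] array
prep_image <- function(img) {
  if (length(dim(img)) == 2L) {
    array(rep(img / 255, 3L), c(dim(img), 3L))
  } else img
}

#' Greedy non-maximum suppression
#'
#' Boxes are visited in the caller-supplied order of decreasing score
#' (ties must already be broken deterministically); a box is kept if its
#' IoU with every previously kept box is below `iou_thr`. The operation
#' is idempotent.
#'
#' @param boxes `n x 4` corner matrix.
#' @param scores Numeric scores.
#' @param iou_thr Suppression threshold.
#' @return Integer indices of the kept boxes (in input order).
#' @export
nms_boxes <- function(boxes, scores, iou_thr = 0.5) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(integer())
  keep <- integer()
  for (i in seq_len(nrow(boxes))) {
    ok <- TRUE
    for (j in keep) {
      if (iou_family(boxes[i, , drop = FALSE], boxes[j, , drop = FALSE],
                     "iou") >= iou_thr) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}

# decode one slice's head outputs into a detection data frame
decode_detections <- function(outs, H, W, score_threshold) {
  rows <- list()
  for (out in outs) {
    st <- out$stride
    obj <- stats::plogis(ag_value(out$obj)[, , 1, 1])
    hit <- which(obj >= score_threshold, arr.ind = TRUE)
    if (!nrow(hit)) next
    raw <- ag_value(out$box)[, , , 1, drop = FALSE]
    cx <- (hit[, 2] - 0.5) * st + tanh(raw[cbind(hit, 1L, 1L)]) * st
    cy <- (hit[, 1] - 0.5) * st + tanh(raw[cbind(hit, 2L, 1L)]) * st
    sp <- function(v) log1p(exp(pmin(v, 30))) + pmax(v - 30, 0)
    w <- sp(raw[cbind(hit, 3L, 1L)]) * st
    h <- sp(raw[cbind(hit, 4L, 1L)]) * st
    rows[[length(rows) + 1L]] <- data.frame(
      x1 = pmax(cx - w / 2, 0), y1 = pmax(cy - h / 2, 0),
      x2 = pmin(cx + w / 2, W), y2 = pmin(cy + h / 2, H),
      score = obj[hit])
  }
  if (!length(rows)) {
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), score = numeric()))
  }
  df <- do.call(rbind, rows)
  df[df$x2 > df$x1 & df$y2 > df$y1, , drop = FALSE]
}

#' Run the detector over a patient's SWI stack
#'
#' Per-slice inference followed by class-agnostic NMS and a global
#' truncation to the top `max_candidates_per_patient` detections by
#' score. Only SWI slices are consumed; the phase stack never enters the
#' detection stage. Ties are broken by lower slice index, then
#' lexicographic box coordinates, so results are reproducible.
#'
#' @param model A `"cmb_detector"`.
#' @param swi_stack Nonempty list of `H x W` matrices (0--255 grayscale)
#'   or `H x W x 3` arrays in \[0, 1\].
#' @param score_threshold,nms_iou,max_candidates Overrides of the model
#'   configuration.
#' @return Data frame of detections: `slice_index` (0-based), corner
#'   coordinates clipped to the image, `score`; sorted by descending
#'   score.
#' @export
detect_patient <- function(model, swi_stack,
                           score_threshold = model$cfg$score_threshold,
                           nms_iou = model$cfg$nms_iou,
                           max_candidates = model$cfg$max_candidates_per_patient) {
  stopifnot(inherits(model, "cmb_detector"))
  if (!length(swi_stack)) stop("empty slice stack")
  all_rows <- list()
  for (s in seq_along(swi_stack)) {
    img <- prep_image(swi_stack[[s]])
    d <- dim(img)
    x <- array(img, c(d[1], d[2], 3L, 1L))
    outs <- forward_detector(model, ag_const(x))
    det <- decode_detections(outs, d[1], d[2], score_threshold)
    if (!nrow(det)) next
    ord <- order(-det$score, det$x1, det$y1, det$x2, det$y2)
    det <- det[ord, , drop = FALSE]
    keep <- nms_boxes(as.matrix(det[, c("x1", "y1", "x2", "y2")]),
                      det$score, nms_iou)
    det <- det[keep, , drop = FALSE]
    det$slice_index <- s - 1L
    all_rows[[length(all_rows) + 1L]] <- det
  }
  if (!length(all_rows)) {
    return(data.frame(slice_index = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), score = numeric()))
  }
  df <- do.call(rbind, all_rows)
  df <- df[order(-df$score, df$slice_index, df$x1, df$y1, df$x2, df$y2), ,
           drop = FALSE]
  df <- utils::head(df, max_candidates)
  rownames(df) <- NULL
  df[, c("slice_index", "x1", "y1", "x2", "y2", "score")]
}
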