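#' Candidate volume for the classification stage
#'
#' The unit the classifier consumes: a three-channel crop stack of four
#' slices in the fixed order (SWI i-1, SWI i, SWI i+1, phase i), centered
#' on a detected candidate. Values are scaled to \[0, 1\]. Neighbor
#' slices missing at stack edges are zero-padded and flagged.
#'
#' @param swi_prev,swi_cur,swi_next,phase_cur `H x W` crop matrices on the
#'   0--255 scale (`NULL` for a missing neighbor slice).
#' @return An array of shape `(3, 4, H, W)` of class `"candidate_volume"`
#'   with attribute `padded` (logical length 4).
#' @export
candidate_volume <- function(swi_prev, swi_cur, swi_next, phase_cur) {
  stopifnot(!is.null(swi_cur), !is.null(phase_cur))
  d <- dim(swi_cur)
  zero <- matrix(0, d[1], d[2])
  slices <- list(swi_prev %||% zero, swi_cur, swi_next %||% zero, phase_cur)
  padded <- c(is.null(swi_prev), FALSE, is.null(swi_next), FALSE)
  v <- array(0, c(3L, 4L, d[1], d[2]))
  for (t in 1:4) {
    m <- pmin(pmax(slices[[t]], 0), 255) / 255
    for (c in 1:3) v[c, t, , ] <- m
  }
  structure(v, padded = padded, class = c("candidate_volume", "array"))
}

#' Classifier configuration
#'
#' The classifier fuses a 3D image branch over the candidate volume with
#' encoded text prompts and classifies through a transformer encoder.
#' Variant `"S"` uses encoder depth 4 with a 256-wide token model;
#' variant `"B"` depth 8 with 512 (about a 4x parameter ratio). All
#' widths can be overridden for small-scale experiments.
#'
#' @param variant `"S"` or `"B"`.
#' @param embed_channels Channels after the second 3D convolution
#'   (default 512); must be divisible by 4 and by `heads`.
#' @param heads Attention heads in the transformer encoder.
#' @param depth Encoder blocks (defaults from `variant`).
#' @param model_dim Token width of the transformer encoder (defaults from
#'   `variant`).
#' @param with_text If `FALSE`, the image-text fusion step is skipped
#'   entirely and image tokens flow directly to the classifier head.
#' @param crop_mode `"fixed32"`, `"fixed64"` (crop windows of side 32/64
#'   at native resolution) or `"dynamic"` (native detection-box sizes,
#'   padded per batch).
#' @param image_branch_mode `"volumetric"` (default: true 3D processing
#'   of the 4-slice volume) or `"averaged2d"` (slices averaged into one
#'   2D image first; loses the phase-vs-SWI distinction).
#' @param threshold Decision threshold on the CMB probability.
#' @param seed Parameter-initialization seed.
#' @return A list of class `"cf_config"`.
#' @export
cf_config <- function(variant = c("S", "B"), embed_channels = 512L,
                      heads = 8L, depth = NULL, model_dim = NULL,
                      with_text = TRUE,
                      crop_mode = c("fixed64", "fixed32", "dynamic"),
                      image_branch_mode = c("volumetric", "averaged2d"),
                      threshold = 0.5, seed = 1L) {
  variant <- match.arg(variant)
  crop_mode <- match.arg(crop_mode)
  image_branch_mode <- match.arg(image_branch_mode)
  depth <- depth %||% if (variant == "S") 4L else 8L
  model_dim <- model_dim %||% if (variant == "S") 256L else 512L
  stopifnot(embed_channels %% 4L == 0L, model_dim %% heads == 0L,
            depth >= 1L, threshold > 0, threshold < 1)
  structure(list(variant = variant, embed_channels = as.integer(embed_channels),
                 heads = as.integer(heads), depth = as.integer(depth),
                 model_dim = as.integer(model_dim), with_text = with_text,
                 crop_mode = crop_mode, image_branch_mode = image_branch_mode,
                 threshold = threshold, seed = as.integer(seed)),
            class = "cf_config")
}

crop_side <- function(cfg) switch(cfg$crop_mode, fixed32 = 32L, fixed64 = 64L,
                                  dynamic = 64L)

#' Build the multimodal classifier
#'
#' @param cfg A [cf_config()].
#' @return A model of class `"cmbsformer"`.
#' @export
build_cmbsformer <- function(cfg) {
  stopifnot(inherits(cfg, "cf_config"))
  with_seed(cfg$seed, {
    C <- cfg$embed_channels
    c1 <- max(4L, C %/% 4L)
    Tn <- if (cfg$image_branch_mode == "volumetric") 4L else 1L
    CT <- C * Tn
    side <- crop_side(cfg)
    g <- side %/% 4L
    d <- cfg$model_dim
    model <- list(
      cfg = cfg, Tn = Tn, CT = CT, base_grid = g,
      conv1 = layer_conv3d(3L, c1, k = 3L, stride = 2L),
      bn1 = layer_bn(c1),
      conv2 = layer_conv3d(c1, C, k = 3L, stride = 2L),
      bn2 = layer_bn(C),
      pos1 = ag_param(array(stats::rnorm(g * g * Tn * C, 0, 0.02),
                            c(g * g, Tn * C))),
      txt_proj = if (cfg$with_text) layer_linear(768L, CT) else NULL,
      # the mixing convolution sits inside a zero-gated residual
      # (ReZero-style): fused = image + gate * conv([image; text]) with
      # the scalar gate initialized at 0. Fusion starts as an exact
      # no-op, contributes nothing to early gradients, and enters only
      # as fast as it reduces the loss -- so the multimodal model never
      # begins worse than its image-only core
      fuse_conv = if (cfg$with_text) layer_linear(2L * CT, CT) else NULL,
      fuse_gate = if (cfg$with_text) ag_param(0) else NULL,
      conv3 = layer_conv3d(C, C, k = 3L, stride = 1L),
      bn3 = layer_bn(C),
      tok_proj = layer_linear(CT, d),
      cls_token = ag_param(matrix(stats::rnorm(d, 0, 0.02), d, 1)),
      pos2 = ag_param(matrix(stats::rnorm(d * (g * g + 1L), 0, 0.02),
                             d, g * g + 1L)),
      blocks = lapply(seq_len(cfg$depth),
                      function(i) layer_transformer_block(d, cfg$heads)),
      head_ln = layer_ln(d),
      head = layer_linear(d, 1L))
    class(model) <- "cmbsformer"
    model
  })
}

#' @export
print.cmbsformer <- function(x, ...) {
  cat(sprintf(paste0("<classifier variant %s: embed %d, token dim %d, ",
                     "depth %d, %s, %s crops, %d parameters>\n"),
              x$cfg$variant, x$cfg$embed_channels, x$cfg$model_dim,
              x$cfg$depth,
              if (x$cfg$with_text) "image+text" else "image-only",
              x$cfg$crop_mode, n_params(x)))
  invisible(x)
}

# stack candidate volumes (3, 4, H, W) into the conv3d layout (H, W, T, C, N);
# averaged2d mode collapses the slice axis first.
volumes_to_batch <- function(volumes, mode) {
  d <- dim(volumes[[1]])
  H <- d[3]; W <- d[4]
  Tn <- if (mode == "volumetric") 4L else 1L
  x <- array(0, c(H, W, Tn, 3L, length(volumes)))
  for (n in seq_along(volumes)) {
    v <- unclass(volumes[[n]])
    if (mode == "volumetric") {
      x[, , , , n] <- aperm(v, c(3, 4, 2, 1))
    } else {
      x[, , 1L, , n] <- aperm(apply(v, c(1, 3, 4), mean), c(2, 3, 1))
    }
  }
  x
}

# image branch on ag node x: (H, W, T, 3, N) -> token node (CT, S, N)
forward_image_branch <- function(model, x) {
  d <- dim(ag_value(x))
  H <- d[1]; W <- d[2]
  if (H %% 4L != 0L || W %% 4L != 0L) {
    stop("crop height and width must be divisible by 4 (two stride-2 stages)")
  }
  h <- ag_gelu(forward_bn(model$bn1, forward_conv3d(model$conv1, x)))
  h <- forward_bn(model$bn2, forward_conv3d(model$conv2, h))
  dd <- dim(ag_value(h))                     # (H/4, W/4, T, C, N)
  Hp <- dd[1]; Wp <- dd[2]; Tn <- dd[3]; C <- dd[4]; N <- dd[5]
  # learned additive position embedding, spatially resized when the crop
  # geometry differs from the configured grid
  pos <- model$pos1
  if (Hp * Wp != model$base_grid^2) {
    U <- interp_matrix(Hp, Wp, model$base_grid, "bilinear")
    pos <- ag_matmul(ag_const(U), pos)
  }
  posv <- ag_reshape(pos, c(Hp, Wp, Tn, C))
  posb <- ag_index_select(posv, rep(seq_len(Hp * Wp * Tn * C), times = N),
                          out_dim = c(Hp, Wp, Tn, C, N))
  h <- ag_add(h, posb)
  # merge channels x slices into the token-channel axis, flatten space
  h <- ag_aperm(h, c(4, 3, 1, 2, 5))         # (C, T, H', W', N)
  ag_reshape(h, c(C * Tn, Hp * Wp, N))       # (CT, S, N)
}

#' Image-branch token sequence
#'
#' Two 3D convolution blocks with spatial stride 2 each (slice stride 1):
#' normalization and GELU after the first, normalization after the
#' second; an additive learned position embedding; then channels and
#' slices are merged into the token-channel axis and space is flattened.
#' For a 64 x 64 crop the spatial grid side drops from 64 to 16 and the
#' channel count rises from 3 to `embed_channels`.
#'
#' @param model A `"cmbsformer"`.
#' @param volumes List of [candidate_volume()] arrays.
#' @return Numeric array `(CT, S, N)`: `embed_channels * slices` token
#'   channels, `(H/4) * (W/4)` tokens, batch.
#' @export
cf_image_branch <- function(model, volumes) {
  x <- volumes_to_batch(volumes, model$cfg$image_branch_mode)
  ag_value(forward_image_branch(model, ag_const(x)))
}

# fuse text into image tokens for ONE sample.
# img: (CT, S) node; text: 768 x n matrix (constant).
forward_fuse <- function(model, img, text) {
  S <- ncol(ag_value(img))
  n <- ncol(text)
  cols <- forward_linear(model$txt_proj, ag_const(text))     # (CT, n)
  tvec <- ag_matmul(cols, matrix(1 / n, n, 1))               # statement mean
  tmap <- ag_matmul(tvec, matrix(1, 1, S))                   # broadcast
  corr <- forward_linear(model$fuse_conv, ag_rbind(img, tmap))
  ag_add(img, ag_mul(corr, model$fuse_gate))
}

# classification head for ONE sample's fused (CT, S) tokens; returns logit
forward_classify <- function(model, tokens, Hp, Wp) {
  cfg <- model$cfg
  # 3D convolution over the fused volume, then flatten (transformer step)
  vol <- ag_reshape(tokens, c(cfg$embed_channels, model$Tn, Hp, Wp, 1L))
  vol <- ag_aperm(vol, c(3, 4, 2, 1, 5))
  vol <- ag_gelu(forward_bn(model$bn3, forward_conv3d(model$conv3, vol)))
  vol <- ag_aperm(vol, c(4, 3, 1, 2, 5))
  flat <- ag_reshape(vol, c(model$CT, Hp * Wp))
  tok <- forward_linear(model$tok_proj, flat)                # (d, S)
  pos <- model$pos2
  S0 <- ncol(ag_value(pos)) - 1L
  pos_sp <- ag_cols(pos, 1L + seq_len(S0))
  if (S0 != Hp * Wp) {
    U <- interp_matrix(Hp, Wp, as.integer(sqrt(S0)), "bilinear")
    pos_sp <- ag_t(ag_matmul(ag_const(U), ag_t(pos_sp)))
  }
  x <- ag_cbind(ag_add(model$cls_token, ag_cols(pos, 1L)),
                ag_add(tok, pos_sp))                         # (d, S+1)
  for (b in model$blocks) x <- forward_transformer_block(b, x)
  h <- forward_ln(model$head_ln, ag_cols(x, 1L))
  forward_linear(model$head, h)                              # (1, 1) logit
}

# full forward: returns list of per-sample logit nodes
forward_cmbsformer <- function(model, volumes, texts = NULL) {
  cfg <- model$cfg
  if (cfg$with_text) {
    if (is.null(texts) || length(texts) != length(volumes)) {
      stop("with_text classifier requires one text embedding per volume")
    }
    for (t in texts) if (nrow(t) != 768L) stop("text embedding width must be 768")
  }
  x <- volumes_to_batch(volumes, cfg$image_branch_mode)
  toks <- forward_image_branch(model, ag_const(x))           # (CT, S, N)
  dd <- dim(ag_value(toks))
  Hp <- dim(ag_value(x))[1] %/% 4L; Wp <- dim(ag_value(x))[2] %/% 4L
  lapply(seq_along(volumes), function(n) {
    img <- ag_reshape(ag_cols(ag_reshape(toks, c(dd[1], dd[2] * dd[3])),
                              (n - 1L) * dd[2] + seq_len(dd[2])),
                      c(dd[1], dd[2]))
    fused <- if (cfg$with_text) forward_fuse(model, img, unclass(texts[[n]]))
             else img
    forward_classify(model, fused, Hp, Wp)
  })
}

#' Classify candidate volumes
#'
#' @param model A `"cmbsformer"`.
#' @param volumes List of [candidate_volume()] arrays (equal crop sizes
#'   within one call; `"dynamic"` crops are padded upstream).
#' @param texts List of [encode_prompts()] matrices (required iff the
#'   model was built `with_text`).
#' @param provenance Optional data frame (e.g. detection id, slice index)
#'   carried through to the result.
#' @return Data frame of class `"classification_result"` with
#'   `probability` and `label` (1 = CMB at the configured threshold).
#' @export
classify_candidates <- function(model, volumes, texts = NULL,
                                provenance = NULL) {
  stopifnot(inherits(model, "cmbsformer"), length(volumes) >= 1L)
  logits <- vapply(forward_cmbsformer(model, volumes, texts),
                   function(z) as.numeric(ag_value(z)), numeric(1))
  prob <- stats::plogis(logits)
  out <- data.frame(probability = prob,
                    label = as.integer(prob >= model$cfg$threshold))
  if (!is.null(provenance)) out <- cbind(provenance, out)
  class(out) <- c("classification_result", class(out))
  out
}

#' Train the classifier on labelled candidate crops
#'
#' Seeded Adam training of the full image(+text) model with
#' class-imbalance weighting (positives upweighted by the negative to
#' positive ratio). A validation split is held out and per-epoch
#' sensitivity (TPR) and specificity (TNR) are traced.
#'
#' @param model A `"cmbsformer"` (modified in place).
#' @param volumes List of candidate volumes.
#' @param labels Binary vector (1 = true CMB).
#' @param texts List of text embeddings (required for `with_text`).
#' @param epochs,seed,lr,batch_size Training settings.
#' @param val_fraction Fraction held out for the validation trace.
#' @return List with `model`, `trace` (per-epoch data frame with `loss`,
#'   `val_tpr`, `val_tnr`) and `val_index`.
#' @export
train_classifier <- function(model, volumes, labels, texts = NULL,
                             epochs = 5L, seed = 1L, lr = 1e-3,
                             batch_size = 8L, val_fraction = 0.25) {
  stopifnot(inherits(model, "cmbsformer"), length(volumes) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop(paste0("training set contains a single class; supply both true ",
                "CMBs and mimic candidates (e.g. widen the phantom mimic ",
                "rates)"))
  }
  params <- collect_params(model)
  opt <- adam_init(params, lr = lr)
  trace <- list()
  with_seed(seed, {
    n <- length(volumes)
    val <- sort(sample(n, max(2L, round(n * val_fraction))))
    tr <- setdiff(seq_len(n), val)
    n_pos <- sum(labels[tr] == 1L); n_neg <- sum(labels[tr] == 0L)
    if (n_pos == 0L || n_neg == 0L) {
      stop("validation split left a single-class training set; lower val_fraction")
    }
    w_pos <- n_neg / n_pos
    on.exit(ag_set_training(FALSE), add = TRUE)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      ep_loss <- 0; n_batches <- 0L
      ag_set_training(TRUE)
      for (b0 in seq(1, length(ord), by = batch_size)) {
        sel <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
        ag_zero_grads(params)
        logits <- forward_cmbsformer(model, volumes[sel],
                                     if (!is.null(texts)) texts[sel])
        z <- logits[[1]]
        for (k in seq_along(logits)[-1]) z <- ag_cbind(z, logits[[k]])
        wts <- ifelse(labels[sel] == 1L, w_pos, 1)
        loss <- ag_bce_logits(z, matrix(labels[sel], 1), weights = wts)
        ag_backward(loss)
        clip_gradients(params)
        opt <- adam_step(opt)
        ep_loss <- ep_loss + ag_value(loss); n_batches <- n_batches + 1L
      }
      ag_set_training(FALSE)
      pv <- classify_candidates(model, volumes[val],
                                if (!is.null(texts)) texts[val])
      yv <- labels[val]
      tpr <- if (any(yv == 1L)) mean(pv$label[yv == 1L] == 1L) else NA_real_
      tnr <- if (any(yv == 0L)) mean(pv$label[yv == 0L] == 0L) else NA_real_
      trace[[ep]] <- data.frame(epoch = ep, loss = ep_loss / n_batches,
                                val_tpr = tpr, val_tnr = tnr)
    }
  })
  list(model = model, trace = do.call(rbind, trace), val_index = val)
}
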