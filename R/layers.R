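# Neural-network layers on top of the autograd engine.
#
# Feature-map layout conventions (R is column-major, so the spatial axes
# lead): 2D maps are arrays (H, W, C, N); 3D maps are (H, W, T, C, N).
# Token matrices are (channels, tokens). Convolutions are computed by
# gathering patches into a column matrix (im2col) and multiplying by the
# weight matrix; the gather indices are cached per input geometry.

# ---- initialization ------------------------------------------------------

he_init <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))

# recursively collect ag_param nodes from nested lists/environments
collect_params <- function(x) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "ag_node")) {
      if (o$requires) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (e in o) walk(e)
    }
  }
  walk(x)
  out
}

n_params <- function(x) {
  sum(vapply(collect_params(x), function(p) length(p$value), numeric(1)))
}

# deterministic checksum of all parameter values (order-stable)
param_checksum <- function(x) {
  vals <- unlist(lapply(collect_params(x), function(p) as.numeric(p$value)))
  sum(vals * seq_along(vals) %% 97)
}

# ---- im2col index construction ------------------------------------------

# indices into an (H, W, C) array for k x k patches, stride s, pad p;
# rows ordered (kh, kw, c) with kh fastest; 0 marks zero padding.
im2col_idx_2d <- function(H, W, C, k, s, p) {
  Ho <- (H + 2 * p - k) %/% s + 1L
  Wo <- (W + 2 * p - k) %/% s + 1L
  oh <- rep(seq_len(Ho), times = Wo)
  ow <- rep(seq_len(Wo), each = Ho)
  # top-left corner in unpadded coords
  h0 <- (oh - 1L) * s - p
  w0 <- (ow - 1L) * s - p
  kh <- rep(seq_len(k) - 1L, times = k)
  kw <- rep(seq_len(k) - 1L, each = k)
  # (k2, Ho*Wo) absolute coords
  hh <- outer(kh, h0, `+`) + 1L
  ww <- outer(kw, w0, `+`) + 1L
  valid <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
  base <- hh + H * (ww - 1L)
  base[!valid] <- 0L
  # expand over channels: add HW offset per channel
  k2 <- k * k
  idx <- matrix(0L, k2 * C, Ho * Wo)
  for (c in seq_len(C)) {
    blk <- base
    blk[valid] <- blk[valid] + H * W * (c - 1L)
    idx[((c - 1L) * k2 + 1L):(c * k2), ] <- blk
  }
  list(idx = idx, Ho = Ho, Wo = Wo)
}

# 3D variant on (H, W, T, C): spatial kernel k/stride s/pad p, temporal
# kernel kt, stride 1, pad pt (so T is preserved when pt = (kt-1)/2).
im2col_idx_3d <- function(H, W, T, C, k, s, p, kt, pt) {
  Ho <- (H + 2 * p - k) %/% s + 1L
  Wo <- (W + 2 * p - k) %/% s + 1L
  To <- T + 2L * pt - kt + 1L
  oh <- rep(seq_len(Ho), times = Wo * To)
  ow <- rep(rep(seq_len(Wo), each = Ho), times = To)
  ot <- rep(seq_len(To), each = Ho * Wo)
  h0 <- (oh - 1L) * s - p
  w0 <- (ow - 1L) * s - p
  t0 <- (ot - 1L) - pt
  k3 <- k * k * kt
  kh <- rep(seq_len(k) - 1L, times = k * kt)
  kw <- rep(rep(seq_len(k) - 1L, each = k), times = kt)
  ktt <- rep(seq_len(kt) - 1L, each = k * k)
  hh <- outer(kh, h0, `+`) + 1L
  ww <- outer(kw, w0, `+`) + 1L
  tt <- outer(ktt, t0, `+`) + 1L
  valid <- hh >= 1L & hh <= H & ww >= 1L & ww <= W & tt >= 1L & tt <= T
  base <- hh + H * (ww - 1L) + H * W * (tt - 1L)
  base[!valid] <- 0L
  idx <- matrix(0L, k3 * C, Ho * Wo * To)
  for (c in seq_len(C)) {
    blk <- base
    blk[valid] <- blk[valid] + H * W * T * (c - 1L)
    idx[((c - 1L) * k3 + 1L):(c * k3), ] <- blk
  }
  list(idx = idx, Ho = Ho, Wo = Wo, To = To)
}

# replicate per-sample indices across a batch (zeros stay zero)
batch_idx <- function(idx, per_sample, N) {
  if (N == 1L) return(idx)
  cols <- ncol(idx)
  out <- matrix(0L, nrow(idx), cols * N)
  for (n in seq_len(N)) {
    blk <- idx
    blk[blk > 0L] <- blk[blk > 0L] + per_sample * (n - 1L)
    out[, ((n - 1L) * cols + 1L):(n * cols)] <- blk
  }
  out
}

# ---- layers --------------------------------------------------------------

layer_conv2d <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                         zero_init = FALSE) {
  fan <- k * k * cin
  Wv <- matrix(if (zero_init) 0 else he_init(fan, cout * fan), cout, fan)
  e <- new.env(parent = emptyenv())
  l <- list(type = "conv2d", cin = cin, cout = cout, k = k, s = stride, p = pad,
            params = list(W = ag_param(Wv), b = ag_param(numeric(cout))),
            cache = e)
  l
}

forward_conv2d <- function(l, x) {
  d <- dim(ag_value(x))        # (H, W, C, N)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  key <- paste(H, W, N, sep = "x")
  info <- l$cache[[key]]
  if (is.null(info)) {
    base <- im2col_idx_2d(H, W, C, l$k, l$s, l$p)
    info <- new.env(parent = emptyenv())
    info$idx <- batch_idx(base$idx, H * W * C, N)
    info$Ho <- base$Ho; info$Wo <- base$Wo
    l$cache[[key]] <- info
  }
  cols <- ag_index_select(x, info$idx,
                          out_dim = c(nrow(info$idx), ncol(info$idx)),
                          cache = info)
  out <- ag_add_bias(ag_matmul(l$params$W, cols), l$params$b)
  out <- ag_reshape(out, c(l$cout, info$Ho, info$Wo, N))
  ag_aperm(out, c(2, 3, 1, 4))
}

layer_conv3d <- function(cin, cout, k = 3L, stride = 2L, kt = 3L) {
  fan <- k * k * kt * cin
  Wv <- matrix(he_init(fan, cout * fan), cout, fan)
  e <- new.env(parent = emptyenv())
  list(type = "conv3d", cin = cin, cout = cout, k = k, s = stride,
       p = (k - 1L) %/% 2L, kt = kt, pt = (kt - 1L) %/% 2L,
       params = list(W = ag_param(Wv), b = ag_param(numeric(cout))),
       cache = e)
}

forward_conv3d <- function(l, x) {
  d <- dim(ag_value(x))        # (H, W, T, C, N)
  H <- d[1]; W <- d[2]; T <- d[3]; C <- d[4]; N <- d[5]
  key <- paste(H, W, T, N, sep = "x")
  info <- l$cache[[key]]
  if (is.null(info)) {
    base <- im2col_idx_3d(H, W, T, C, l$k, l$s, l$p, l$kt, l$pt)
    info <- new.env(parent = emptyenv())
    info$idx <- batch_idx(base$idx, H * W * T * C, N)
    info$Ho <- base$Ho; info$Wo <- base$Wo; info$To <- base$To
    l$cache[[key]] <- info
  }
  cols <- ag_index_select(x, info$idx,
                          out_dim = c(nrow(info$idx), ncol(info$idx)),
                          cache = info)
  out <- ag_add_bias(ag_matmul(l$params$W, cols), l$params$b)
  out <- ag_reshape(out, c(l$cout, info$Ho, info$Wo, info$To, N))
  ag_aperm(out, c(2, 3, 4, 1, 5))
}

layer_bn <- function(c, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$mean <- numeric(c)
  st$var <- rep(1, c)
  st$momentum <- momentum
  list(type = "bn", c = c, stats = st,
       params = list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c))))
}

# x: (H, W, C, N) or (H, W, T, C, N); normalizes per channel. In training
# mode uses batch statistics and updates the running estimates; in eval
# mode applies the running statistics, so candidates in a batch never see
# each other.
forward_bn <- function(l, x) {
  d <- dim(ag_value(x))
  nd <- length(d)
  C <- d[nd - 1L]; N <- d[nd]
  sp <- prod(d[seq_len(nd - 2L)])
  perm <- c(nd - 1L, seq_len(nd - 2L), nd)
  xt <- ag_aperm(x, perm)                   # (C, spatial..., N)
  xm <- ag_reshape(xt, c(C, sp * N))
  if (isTRUE(.ag$training)) {
    v <- ag_value(xm)
    mu <- rowMeans(v)
    va <- rowMeans((v - mu)^2)
    m <- l$stats$momentum
    l$stats$mean <- (1 - m) * l$stats$mean + m * mu
    l$stats$var <- (1 - m) * l$stats$var + m * va
    y <- ag_bn_cols(xm, l$params$gamma, l$params$beta)
  } else {
    istd <- 1 / sqrt(l$stats$var + 1e-5)
    xc <- ag_add_bias(xm, ag_const(-l$stats$mean))
    y <- ag_add_bias(ag_mul_rows(xc, ag_mul(l$params$gamma, ag_const(istd))),
                     l$params$beta)
  }
  y <- ag_reshape(y, c(C, d[seq_len(nd - 2L)], N))
  ag_aperm(y, order(perm))
}

layer_linear <- function(din, dout, zero_init = FALSE) {
  Wv <- matrix(if (zero_init) 0 else he_init(din, dout * din), dout, din)
  list(type = "linear",
       params = list(W = ag_param(Wv), b = ag_param(numeric(dout))))
}

# x: (din, cols)
forward_linear <- function(l, x) {
  ag_add_bias(ag_matmul(l$params$W, x), l$params$b)
}

layer_ln <- function(c) {
  list(type = "ln", c = c,
       params = list(gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c))))
}

forward_ln <- function(l, x) ag_ln_cols(x, l$params$gamma, l$params$beta)

# ---- pooling / interpolation operators ----------------------------------

# (g*g) x (H*W) averaging matrix for adaptive average pooling
adaptive_avg_matrix <- function(H, W, g) {
  bounds <- function(n) {
    lo <- floor((seq_len(g) - 1L) * n / g) + 1L
    hi <- ceiling(seq_len(g) * n / g)
    cbind(lo, hi)
  }
  bh <- bounds(H); bw <- bounds(W)
  P <- matrix(0, g * g, H * W)
  for (j in seq_len(g)) {
    for (i in seq_len(g)) {
      hs <- bh[i, 1]:bh[i, 2]; ws <- bw[j, 1]:bw[j, 2]
      cells <- as.vector(outer(hs, H * (ws - 1L), `+`))
      P[i + g * (j - 1L), cells] <- 1 / length(cells)
    }
  }
  P
}

# region index list for adaptive max pooling
adaptive_regions <- function(H, W, g) {
  bounds <- function(n) {
    lo <- floor((seq_len(g) - 1L) * n / g) + 1L
    hi <- ceiling(seq_len(g) * n / g)
    cbind(lo, hi)
  }
  bh <- bounds(H); bw <- bounds(W)
  regions <- vector("list", g * g)
  for (j in seq_len(g)) {
    for (i in seq_len(g)) {
      hs <- bh[i, 1]:bh[i, 2]; ws <- bw[j, 1]:bw[j, 2]
      regions[[i + g * (j - 1L)]] <- as.vector(outer(hs, H * (ws - 1L), `+`))
    }
  }
  regions
}

# adaptive max pool: x (HW, M) matrix node -> (g^2, M) via per-region argmax
ag_adaptive_max <- function(x, regions) {
  v <- ag_value(x)
  M <- ncol(v)
  ncell <- length(regions)
  idx <- matrix(0L, ncell, M)
  for (i in seq_len(ncell)) {
    r <- regions[[i]]
    sub <- v[r, , drop = FALSE]
    am <- max.col(t(sub), ties.method = "first")
    idx[i, ] <- r[am] + nrow(v) * (seq_len(M) - 1L)
  }
  ag_index_select(x, idx, out_dim = c(ncell, M))
}

# (H*W) x (g*g) bilinear interpolation matrix from a g x g token grid
interp_matrix <- function(H, W, g, mode = c("bilinear", "nearest")) {
  mode <- match.arg(mode)
  # pixel centers mapped into source grid coordinates (align_corners = FALSE)
  src <- function(n) {
    s <- (seq_len(n) - 0.5) * g / n - 0.5
    pmin(pmax(s, 0), g - 1)
  }
  sh <- src(H); sw <- src(W)
  P <- matrix(0, H * W, g * g)
  for (w in seq_len(W)) {
    x0 <- floor(sw[w]); fx <- sw[w] - x0
    for (h in seq_len(H)) {
      y0 <- floor(sh[h]); fy <- sh[h] - y0
      px <- h + H * (w - 1L)
      if (mode == "nearest") {
        gi <- round(sh[h]) + 1L; gj <- round(sw[w]) + 1L
        P[px, gi + g * (gj - 1L)] <- 1
      } else {
        for (dy in 0:1) for (dx in 0:1) {
          gi <- min(y0 + dy, g - 1) + 1L
          gj <- min(x0 + dx, g - 1) + 1L
          wgt <- (if (dy == 0) 1 - fy else fy) * (if (dx == 0) 1 - fx else fx)
          P[px, gi + g * (gj - 1L)] <- P[px, gi + g * (gj - 1L)] + wgt
        }
      }
    }
  }
  P
}

# nearest 2x upsampling of (H, W, C, N); index sets memoized per geometry
.upsample_memo <- new.env(parent = emptyenv())

ag_upsample2x <- function(x) {
  d <- dim(ag_value(x))
  H <- d[1]; W <- d[2]
  M <- d[3] * d[4]
  key <- paste(H, W, M, sep = "x")
  info <- .upsample_memo[[key]]
  if (is.null(info)) {
    rows <- rep(seq_len(H), each = 2L)
    cols <- rep(seq_len(W), each = 2L)
    hw <- as.vector(outer(rows, H * (cols - 1L), `+`))
    info <- new.env(parent = emptyenv())
    info$idx <- outer(hw, H * W * (seq_len(M) - 1L), `+`)
    .upsample_memo[[key]] <- info
  }
  xm <- ag_reshape(x, c(H * W, M))
  y <- ag_index_select(xm, info$idx, out_dim = c(4L * H * W, M), cache = info)
  ag_reshape(y, c(2L * H, 2L * W, d[3], d[4]))
}

# ---- multi-head attention ------------------------------------------------

layer_mha <- function(c, heads, zero_out = TRUE) {
  stopifnot(c %% heads == 0L)
  list(type = "mha", c = c, heads = heads,
       params = list(
         Wq = ag_param(matrix(he_init(c, c * c), c, c)),
         Wk = ag_param(matrix(he_init(c, c * c), c, c)),
         Wv = ag_param(matrix(he_init(c, c * c), c, c)),
         Wo = ag_param(matrix(if (zero_out) 0 else he_init(c, c * c), c, c)),
         bq = ag_param(numeric(c)), bk = ag_param(numeric(c)),
         bv = ag_param(numeric(c)), bo = ag_param(numeric(c))))
}

ag_rows <- function(a, i) {
  a <- ag_wrap(a)
  out <- ag_node(a$value[i, , drop = FALSE], list(a))
  adim <- dim(a$value)
  out$backfn <- function(g) {
    acc <- array(0, adim)
    acc[i, ] <- acc[i, ] + g
    ag_accum(a, acc)
  }
  out
}

ag_t <- function(a) ag_aperm(a, c(2, 1))

# q: (C, Sq), kv: (C, Sk) token matrices for one sample.
# Returns list(out = (C, Sq), attn = row-stochastic (heads*Sq, Sk) value).
forward_mha <- function(l, q, kv) {
  C <- l$c; h <- l$heads; dh <- C %/% h
  Q <- ag_add_bias(ag_matmul(l$params$Wq, q), l$params$bq)
  K <- ag_add_bias(ag_matmul(l$params$Wk, kv), l$params$bk)
  V <- ag_add_bias(ag_matmul(l$params$Wv, kv), l$params$bv)
  outs <- NULL
  attn_rows <- list()
  for (i in seq_len(h)) {
    rows <- ((i - 1L) * dh + 1L):(i * dh)
    Qh <- ag_rows(Q, rows); Kh <- ag_rows(K, rows); Vh <- ag_rows(V, rows)
    scores <- ag_scale(ag_matmul(ag_t(Qh), Kh), 1 / sqrt(dh))
    A <- ag_softmax_rows(scores)              # (Sq, Sk)
    attn_rows[[i]] <- ag_value(A)
    Oh <- ag_t(ag_matmul(A, ag_t(Vh)))        # (dh, Sq)
    outs <- if (is.null(outs)) Oh else ag_rbind(outs, Oh)
  }
  out <- ag_add_bias(ag_matmul(l$params$Wo, outs), l$params$bo)
  list(out = out, attn = do.call(rbind, attn_rows))
}

# ---- transformer encoder block (pre-LN) ---------------------------------

layer_transformer_block <- function(c, heads, mlp_ratio = 2L) {
  list(type = "tblock",
       ln1 = layer_ln(c),
       mha = layer_mha(c, heads, zero_out = FALSE),
       ln2 = layer_ln(c),
       fc1 = layer_linear(c, c * mlp_ratio),
       fc2 = layer_linear(c * mlp_ratio, c))
}

# x: (C, S) token matrix for one sample
forward_transformer_block <- function(l, x) {
  h <- forward_ln(l$ln1, x)
  x <- ag_add(x, forward_mha(l$mha, h, h)$out)
  h <- forward_ln(l$ln2, x)
  h <- forward_linear(l$fc2, ag_gelu(forward_linear(l$fc1, h)))
  ag_add(x, h)
}
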