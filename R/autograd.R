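# Reverse-mode automatic differentiation on dense arrays.
#
# A minimal tape: every operation returns an `ag_node` environment holding
# the forward value, its parents, and a closure that scatters the incoming
# gradient to the parents. `ag_backward()` walks nodes in reverse creation
# order, which is a valid topological order because the tape is append-only.
# Only nodes that (transitively) depend on a parameter carry gradients.
#
# The engine is deliberately small: just the primitives the detector,
# saliency-attention block and multimodal classifier need. Every primitive
# is validated against central finite differences in the test suite.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0
.ag$training <- FALSE

# training mode switches batch normalization from running statistics to
# batch statistics (and enables their update)
ag_set_training <- function(flag) {
  old <- .ag$training
  .ag$training <- isTRUE(flag)
  invisible(old)
}

ag_node <- function(value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$parents <- parents
  n$backfn <- backfn
  n$grad <- NULL
  .ag$counter <- .ag$counter + 1
  n$id <- .ag$counter
  n$requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  class(n) <- "ag_node"
  n
}

#' Create a trainable parameter node
#' @param value Numeric array of initial values.
#' @return An `ag_node` that accumulates gradients.
#' @keywords internal
#' @export
ag_param <- function(value) {
  n <- ag_node(value)
  n$requires <- TRUE
  n
}

ag_const <- function(value) ag_node(value)

ag_wrap <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

#' @export
print.ag_node <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf("<ag_node id=%d dim=[%s] requires=%s>\n", x$id,
              paste(if (is.null(d)) length(x$value) else d, collapse = ","),
              x$requires))
  invisible(x)
}

#' Extract the forward value of a node
#' @param x An `ag_node` (plain numerics pass through).
#' @keywords internal
#' @export
ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

ag_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run backpropagation from a scalar (or seeded) output node
#' @param out Output `ag_node`.
#' @param seed Gradient seed; defaults to 1 for scalar outputs.
#' @keywords internal
#' @export
ag_backward <- function(out, seed = NULL) {
  if (is.null(seed)) {
    stopifnot(length(out$value) == 1L)
    seed <- 1
  }
  # collect the reachable subgraph that requires gradients
  seen <- new.env(parent = emptyenv())
  stack <- list(out)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]]) || !n$requires) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  out$grad <- seed
  for (n in nodes[ord]) {
    if (!is.null(n$backfn) && !is.null(n$grad)) n$backfn(n$grad)
  }
  invisible(out)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- arithmetic ----------------------------------------------------------

ag_add <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  out <- ag_node(a$value + b$value, list(a, b))
  la <- length(a$value); lb <- length(b$value)
  out$backfn <- function(g) {
    ag_accum(a, if (la == 1L && length(g) > 1L) sum(g) else g)
    ag_accum(b, if (lb == 1L && length(g) > 1L) sum(g) else g)
  }
  out
}

ag_sub <- function(a, b) ag_add(a, ag_scale(b, -1))

ag_mul <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  out <- ag_node(a$value * b$value, list(a, b))
  la <- length(a$value); lb <- length(b$value)
  out$backfn <- function(g) {
    ga <- g * b$value; gb <- g * a$value
    ag_accum(a, if (la == 1L && length(ga) > 1L) sum(ga) else ga)
    ag_accum(b, if (lb == 1L && length(gb) > 1L) sum(gb) else gb)
  }
  out
}

ag_div <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  out <- ag_node(a$value / b$value, list(a, b))
  la <- length(a$value); lb <- length(b$value)
  out$backfn <- function(g) {
    ga <- g / b$value
    gb <- -g * a$value / b$value^2
    ag_accum(a, if (la == 1L && length(ga) > 1L) sum(ga) else ga)
    ag_accum(b, if (lb == 1L && length(gb) > 1L) sum(gb) else gb)
  }
  out
}

ag_scale <- function(a, s) {
  a <- ag_wrap(a)
  out <- ag_node(a$value * s, list(a))
  out$backfn <- function(g) ag_accum(a, g * s)
  out
}

ag_matmul <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  out <- ag_node(a$value %*% b$value, list(a, b))
  out$backfn <- function(g) {
    ag_accum(a, tcrossprod(g, b$value))
    ag_accum(b, crossprod(a$value, g))
  }
  out
}

# add a length-nrow vector to every column of a matrix
ag_add_bias <- function(a, bias) {
  a <- ag_wrap(a); bias <- ag_wrap(bias)
  out <- ag_node(a$value + bias$value, list(a, bias))
  out$backfn <- function(g) {
    ag_accum(a, g)
    ag_accum(bias, rowSums(g))
  }
  out
}

# ---- shape ---------------------------------------------------------------

ag_reshape <- function(a, dims) {
  a <- ag_wrap(a)
  olddim <- dim(a$value)
  oldlen <- length(a$value)
  v <- a$value
  dim(v) <- dims
  out <- ag_node(v, list(a))
  out$backfn <- function(g) {
    if (is.null(olddim)) { dim(g) <- NULL; length(g) <- oldlen } else dim(g) <- olddim
    ag_accum(a, g)
  }
  out
}

ag_aperm <- function(a, perm) {
  a <- ag_wrap(a)
  out <- ag_node(aperm(a$value, perm), list(a))
  inv <- order(perm)
  out$backfn <- function(g) ag_accum(a, aperm(g, inv))
  out
}

# gather by linear index; idx == 0 yields 0 (used for zero padding).
# `cache`: optional environment in which the transposed scatter operator
# (a sparse matrix) is memoized -- worthwhile whenever the same index set
# is reused across training steps (im2col, upsampling).
ag_index_select <- function(a, idx, out_dim = NULL, cache = NULL) {
  a <- ag_wrap(a)
  pos <- idx > 0L
  all_pos <- all(pos)
  if (all_pos) {
    v <- a$value[as.vector(idx)]   # force linear indexing
  } else {
    v <- numeric(length(idx))
    v[pos] <- a$value[idx[pos]]
  }
  if (!is.null(out_dim)) dim(v) <- out_dim
  out <- ag_node(v, list(a))
  alen <- length(a$value); adim <- dim(a$value)
  out$backfn <- function(g) {
    g <- as.numeric(g)
    if (!is.null(cache)) {
      M <- cache$scatter
      if (is.null(M)) {
        M <- Matrix::sparseMatrix(i = idx[pos], j = which(pos),
                                  x = 1, dims = c(alen, length(idx)))
        cache$scatter <- M
      }
      acc <- as.numeric(M %*% g)
    } else {
      acc <- numeric(alen)
      s <- rowsum(g[pos], idx[pos])
      acc[as.integer(rownames(s))] <- s
    }
    if (!is.null(adim)) dim(acc) <- adim
    ag_accum(a, acc)
  }
  out
}

ag_rbind <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  na <- nrow(a$value)
  out <- ag_node(rbind(a$value, b$value), list(a, b))
  out$backfn <- function(g) {
    ag_accum(a, g[seq_len(na), , drop = FALSE])
    ag_accum(b, g[-seq_len(na), , drop = FALSE])
  }
  out
}

ag_cbind <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  na <- ncol(a$value)
  out <- ag_node(cbind(a$value, b$value), list(a, b))
  out$backfn <- function(g) {
    ag_accum(a, g[, seq_len(na), drop = FALSE])
    ag_accum(b, g[, -seq_len(na), drop = FALSE])
  }
  out
}

ag_cols <- function(a, j) {
  a <- ag_wrap(a)
  out <- ag_node(a$value[, j, drop = FALSE], list(a))
  adim <- dim(a$value)
  out$backfn <- function(g) {
    acc <- array(0, adim)
    acc[, j] <- acc[, j] + g
    ag_accum(a, acc)
  }
  out
}

# ---- nonlinearities ------------------------------------------------------

ag_unary <- function(a, f, df) {
  a <- ag_wrap(a)
  out <- ag_node(f(a$value), list(a))
  out$backfn <- function(g) ag_accum(a, g * df(a$value, out$value))
  out
}

ag_relu <- function(a) ag_unary(a, function(x) pmax(x, 0),
                                function(x, y) as.numeric(x > 0))
ag_sigmoid <- function(a) ag_unary(a, stats::plogis,
                                   function(x, y) y * (1 - y))
ag_tanh <- function(a) ag_unary(a, tanh, function(x, y) 1 - y^2)
ag_silu <- function(a) ag_unary(a, function(x) x * stats::plogis(x),
                                function(x, y) {
                                  s <- stats::plogis(x); s * (1 + x * (1 - s))
                                })
ag_gelu <- function(a) ag_unary(a, function(x) x * stats::pnorm(x),
                                function(x, y) stats::pnorm(x) + x * stats::dnorm(x))
ag_exp <- function(a) ag_unary(a, exp, function(x, y) y)
ag_sqrt <- function(a) ag_unary(a, sqrt, function(x, y) 0.5 / y)
ag_atan <- function(a) ag_unary(a, atan, function(x, y) 1 / (1 + x^2))
ag_square <- function(a) ag_unary(a, function(x) x^2, function(x, y) 2 * x)
ag_softplus <- function(a) ag_unary(a,
  function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30)))),
  function(x, y) stats::plogis(x))

ag_pmax <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  out <- ag_node(pmax(a$value, b$value), list(a, b))
  la <- length(a$value); lb <- length(b$value)
  out$backfn <- function(g) {
    takea <- a$value >= b$value
    ga <- g * takea; gb <- g * !takea
    ag_accum(a, if (la == 1L && length(ga) > 1L) sum(ga) else ga)
    ag_accum(b, if (lb == 1L && length(gb) > 1L) sum(gb) else gb)
  }
  out
}

ag_pmin <- function(a, b) {
  a <- ag_wrap(a); b <- ag_wrap(b)
  out <- ag_node(pmin(a$value, b$value), list(a, b))
  la <- length(a$value); lb <- length(b$value)
  out$backfn <- function(g) {
    takea <- a$value <= b$value
    ga <- g * takea; gb <- g * !takea
    ag_accum(a, if (la == 1L && length(ga) > 1L) sum(ga) else ga)
    ag_accum(b, if (lb == 1L && length(gb) > 1L) sum(gb) else gb)
  }
  out
}

# ---- reductions & normalizations ----------------------------------------

ag_sum <- function(a) {
  a <- ag_wrap(a)
  out <- ag_node(sum(a$value), list(a))
  adim <- dim(a$value); alen <- length(a$value)
  out$backfn <- function(g) {
    acc <- array(g, if (is.null(adim)) alen else adim)
    ag_accum(a, acc)
  }
  out
}

ag_mean <- function(a) ag_scale(ag_sum(a), 1 / length(ag_value(a)))

# row-wise softmax of a matrix
ag_softmax_rows <- function(a) {
  a <- ag_wrap(a)
  x <- a$value
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  s <- e / rowSums(e)
  out <- ag_node(s, list(a))
  out$backfn <- function(g) {
    ag_accum(a, s * (g - rowSums(g * s)))
  }
  out
}

# batch normalization over columns: each row (channel) normalized across
# all columns (batch x space). Training-mode statistics.
ag_bn_cols <- function(x, gamma, beta, eps = 1e-5) {
  x <- ag_wrap(x); gamma <- ag_wrap(gamma); beta <- ag_wrap(beta)
  v <- x$value
  m <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  var <- rowMeans(xc^2)
  istd <- 1 / sqrt(var + eps)
  xhat <- xc * istd
  out <- ag_node(xhat * gamma$value + beta$value, list(x, gamma, beta))
  out$backfn <- function(g) {
    ag_accum(gamma, rowSums(g * xhat))
    ag_accum(beta, rowSums(g))
    gx <- g * gamma$value
    # d/dx of (x - mu) * istd with mu, istd functions of x
    ag_accum(x, istd * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat)))
  }
  out
}

# multiply each column of a matrix elementwise by a per-row vector
ag_mul_rows <- function(x, v) {
  x <- ag_wrap(x); v <- ag_wrap(v)
  out <- ag_node(x$value * v$value, list(x, v))
  out$backfn <- function(g) {
    ag_accum(x, g * v$value)
    ag_accum(v, rowSums(g * x$value))
  }
  out
}

# layer normalization over rows: each column (token) normalized across
# its channels.
ag_ln_cols <- function(x, gamma, beta, eps = 1e-5) {
  x <- ag_wrap(x); gamma <- ag_wrap(gamma); beta <- ag_wrap(beta)
  v <- x$value
  n <- nrow(v)
  mu <- colMeans(v)
  xc <- sweep(v, 2L, mu)
  var <- colMeans(xc^2)
  istd <- 1 / sqrt(var + eps)
  xhat <- sweep(xc, 2L, istd, `*`)
  out <- ag_node(xhat * gamma$value + beta$value, list(x, gamma, beta))
  out$backfn <- function(g) {
    ag_accum(gamma, rowSums(g * xhat))
    ag_accum(beta, rowSums(g))
    gx <- g * gamma$value
    t1 <- sweep(gx, 2L, colMeans(gx))
    t2 <- sweep(xhat, 2L, colMeans(gx * xhat), `*`)
    ag_accum(x, sweep(t1 - t2, 2L, istd, `*`))
  }
  out
}

# numerically stable binary cross-entropy on logits; mean over elements
ag_bce_logits <- function(z, target, weights = NULL) {
  z <- ag_wrap(z)
  t <- as.numeric(ag_value(target))
  zv <- as.numeric(z$value)
  w <- if (is.null(weights)) rep(1, length(zv)) else as.numeric(weights)
  per <- pmax(zv, 0) - zv * t + log1p(exp(-abs(zv)))
  out <- ag_node(sum(w * per) / sum(w), list(z))
  zdim <- dim(z$value)
  out$backfn <- function(g) {
    gz <- g * w * (stats::plogis(zv) - t) / sum(w)
    if (!is.null(zdim)) dim(gz) <- zdim
    ag_accum(z, gz)
  }
  out
}

# ---- Adam optimizer ------------------------------------------------------

#' Adam optimizer state over a parameter list
#' @param params List of `ag_param` nodes.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment constants.
#' @keywords internal
#' @export
adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(params = params, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0,
       m = lapply(params, function(p) p$value * 0),   # preserves dim structure
       v = lapply(params, function(p) p$value * 0))
}

# rescale all gradients so their global L2 norm is at most max_norm
clip_gradients <- function(params, max_norm = 5) {
  ss <- 0
  for (p in params) if (!is.null(p$grad)) ss <- ss + sum(p$grad^2)
  nrm <- sqrt(ss)
  if (is.finite(nrm) && nrm > max_norm) {
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * (max_norm / nrm)
  }
  invisible(nrm)
}

#' @rdname adam_init
#' @param opt Optimizer state from [adam_init()].
#' @export
adam_step <- function(opt) {
  opt$t <- opt$t + 1
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad
    if (is.null(dim(p$value))) dim(g) <- NULL
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g^2
    mhat <- opt$m[[i]] / (1 - opt$beta1^opt$t)
    vhat <- opt$v[[i]] / (1 - opt$beta2^opt$t)
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
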