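#' Saliency multi-head attention block configuration
#'
#' The block builds *query* tokens by adaptive max pooling of the feature
#' map (max pooling picks up salient extremes, e.g. the strong local
#' responses that hypointense microbleeds leave on SWI feature maps) and
#' *key/value* tokens by adaptive average pooling (a smoothed "background
#' board" of local context). Multi-head scaled-dot-product attention then
#' relates each salient query to the background, and the attended tokens
#' are interpolated back onto the spatial grid and added to the input as a
#' residual. With the output projection zero-initialized the block is an
#' exact identity at insertion time, so it can be dropped into any
#' convolutional backbone without perturbing it.
#'
#' @param channels Number of feature channels; must be divisible by `heads`.
#' @param heads Number of attention heads (default 4).
#' @param query_grid Side length of the max-pooled query token grid
#'   (default 4, i.e. 16 query tokens).
#' @param key_grid Side length of the average-pooled key/value token grid
#'   (default 8, i.e. 64 background tokens).
#' @param interp `"bilinear"` (default) or `"nearest"` interpolation when
#'   mapping attended tokens back to the spatial grid.
#' @return A list of class `"saliency_attention_config"`.
#' @export
saliency_attention_config <- function(channels, heads = 4L, query_grid = 4L,
                                      key_grid = 8L,
                                      interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(channels >= 1L, heads >= 1L, query_grid >= 1L, key_grid >= 1L)
  if (channels %% heads != 0L) stop("channels must be divisible by heads")
  structure(list(channels = as.integer(channels), heads = as.integer(heads),
                 query_grid = as.integer(query_grid),
                 key_grid = as.integer(key_grid), interp = interp),
            class = "saliency_attention_config")
}

#' Build a saliency attention block
#'
#' @param cfg A [saliency_attention_config()].
#' @return A module list holding the attention projections (the output
#'   projection is zero-initialized so the untrained block is the identity).
#' @seealso [cmbs_mha_forward()], [saliency_parameter_count()]
#' @export
cmbs_mha <- function(cfg) {
  stopifnot(inherits(cfg, "saliency_attention_config"))
  structure(list(cfg = cfg,
                 mha = layer_mha(cfg$channels, cfg$heads, zero_out = TRUE),
                 cache = new.env(parent = emptyenv())),
            class = "cmbs_mha")
}

# internal forward on ag nodes; x: (H, W, C, N)
forward_saliency <- function(mod, x) {
  cfg <- mod$cfg
  d <- dim(ag_value(x))
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (C != cfg$channels) {
    stop(sprintf("feature map has %d channels but the block expects %d",
                 C, cfg$channels))
  }
  if (cfg$query_grid > min(H, W) || cfg$key_grid > min(H, W)) {
    stop("token grid larger than the feature map's spatial extent")
  }
  key <- paste(H, W, sep = "x")
  ops <- mod$cache[[key]]
  if (is.null(ops)) {
    ops <- list(avgP = adaptive_avg_matrix(H, W, cfg$key_grid),
                regions = adaptive_regions(H, W, cfg$query_grid),
                up = interp_matrix(H, W, cfg$query_grid, cfg$interp))
    mod$cache[[key]] <- ops
  }
  xm <- ag_reshape(x, c(H * W, C * N))
  qtok <- ag_adaptive_max(xm, ops$regions)          # (q^2, C*N)
  ktok <- ag_matmul(ag_const(ops$avgP), xm)         # (k^2, C*N)
  pieces <- NULL
  attn <- vector("list", N)
  for (n in seq_len(N)) {
    cols <- ((n - 1L) * C + 1L):(n * C)
    qn <- ag_t(ag_cols(qtok, cols))                 # (C, q^2)
    kn <- ag_t(ag_cols(ktok, cols))                 # (C, k^2)
    res <- forward_mha(mod$mha, qn, kn)
    attn[[n]] <- res$attn
    yn <- ag_matmul(ag_const(ops$up), ag_t(res$out))  # (HW, C)
    pieces <- if (is.null(pieces)) yn else ag_cbind(pieces, yn)
  }
  out <- ag_add(x, ag_reshape(pieces, c(H, W, C, N)))
  attr(out, "attn") <- attn
  out
}

#' Apply a saliency attention block to a feature map
#'
#' @param mod A module from [cmbs_mha()].
#' @param x Numeric array of shape `(batch, channels, height, width)` --
#'   the conventional batch-first layout -- or `(height, width, channels,
#'   batch)` (the package's internal layout; disambiguated by
#'   `layout`).
#' @param layout `"nchw"` (default) or `"hwcn"`.
#' @return An array of the same shape as `x`.
#' @export
cmbs_mha_forward <- function(mod, x, layout = c("nchw", "hwcn")) {
  layout <- match.arg(layout)
  stopifnot(inherits(mod, "cmbs_mha"), is.array(x), length(dim(x)) == 4L)
  if (any(!is.finite(x))) stop("feature map values must be finite")
  xi <- if (layout == "nchw") aperm(x, c(3, 4, 2, 1)) else x
  out <- ag_value(forward_saliency(mod, ag_const(xi)))
  if (layout == "nchw") aperm(out, c(4, 3, 1, 2)) else out
}

#' Learnable-parameter count of a saliency attention block
#'
#' Four `channels x channels` projections (query, key, value, output) with
#' their bias vectors; the pooled token grids add no parameters.
#'
#' @param cfg A [saliency_attention_config()].
#' @return Integer parameter count, deterministic in the configuration.
#' @export
saliency_parameter_count <- function(cfg) {
  stopifnot(inherits(cfg, "saliency_attention_config"))
  C <- cfg$channels
  4L * (C * C + C)
}

#' @export
print.cmbs_mha <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<saliency attention block: %d channels, %d heads, ",
                     "query grid %dx%d (max), key grid %dx%d (avg), ",
                     "%d parameters>\n"),
              cfg$channels, cfg$heads, cfg$query_grid, cfg$query_grid,
              cfg$key_grid, cfg$key_grid, saliency_parameter_count(cfg)))
  invisible(x)
}
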