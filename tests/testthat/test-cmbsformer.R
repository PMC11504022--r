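# Multimodal classifier: shape contracts, fusion, bypass, training.
# Small widths are used here; the full-width (512-channel) contract is
# exercised once in the acceptance suite.

tiny_cf <- function(...) {
  cf_config("S", embed_channels = 16L, model_dim = 32L, heads = 4L,
            depth = 2L, crop_mode = "fixed32", seed = 6L, ...)
}

rand_volume <- function(seed, side = 32L) {
  set.seed(seed)
  candidate_volume(matrix(runif(side^2, 0, 255), side),
                   matrix(runif(side^2, 0, 255), side),
                   matrix(runif(side^2, 0, 255), side),
                   matrix(runif(side^2, 0, 255), side))
}

rand_text <- function(seed, n = 4L) {
  meta <- patient_meta("p", "male", 60 + seed %% 5)
  p <- build_prompts(meta, box(0, 0, 4 + seed %% 7, 6), seed %% 2 == 0,
                     FALSE)
  encode_prompts(p)[, seq_len(min(n, 4L)), drop = FALSE] |>
    structure(class = c("text_embedding", "matrix"))
}

test_that("candidate volumes have the fixed slice order and padding flags", {
  v <- candidate_volume(NULL, matrix(128, 8, 8), matrix(64, 8, 8),
                        matrix(255, 8, 8))
  expect_identical(dim(v), c(3L, 4L, 8L, 8L))
  expect_identical(attr(v, "padded"), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(max(v), 1)          # scaled to [0, 1]
  expect_equal(unique(as.vector(v[, 1, , ])), 0)  # zero-padded neighbor
  expect_equal(v[1, 2, 1, 1], 128 / 255)
  expect_equal(v[1, 4, 1, 1], 1)   # phase slice is position 4
})

test_that("the image branch halves the grid twice and merges slices", {
  m <- build_cmbsformer(tiny_cf())
  toks <- cf_image_branch(m, list(rand_volume(1), rand_volume(2)))
  # 32 x 32 crop -> 8 x 8 grid = 64 tokens; 16 channels x 4 slices wide
  expect_identical(dim(toks), c(64L, 64L, 2L))
  expect_true(all(is.finite(toks)))
  m2 <- build_cmbsformer(tiny_cf(image_branch_mode = "averaged2d"))
  toks2 <- cf_image_branch(m2, list(rand_volume(1)))
  expect_identical(dim(toks2), c(16L, 64L, 1L))  # single averaged slice
  expect_error(cf_image_branch(m, list(rand_volume(1, side = 30L))),
               "divisible by 4")
})

test_that("fused output shape is independent of the statement count", {
  m <- build_cmbsformer(tiny_cf())
  v <- rand_volume(3)
  r3 <- classify_candidates(m, list(v), list(rand_text(1, 3L)))
  r4 <- classify_candidates(m, list(v), list(rand_text(1, 4L)))
  expect_identical(dim(r3), dim(r4))
  expect_error(classify_candidates(m, list(v),
                                   list(matrix(0, 512, 3))), "768")
})

test_that("the image-only bypass is a distinct path from zeroed text", {
  m <- build_cmbsformer(tiny_cf())
  # fusion initializes as a no-op (identity on image, zero on text); give
  # the text path nonzero weight as training would, so the structural
  # difference between zeroed text and the bypass becomes observable
  set.seed(41)
  m$txt_proj$params$b$value <- rnorm(length(m$txt_proj$params$b$value), 0, 0.1)
  m$fuse_gate$value <- 0.5
  v <- rand_volume(4)
  with_zero_text <- classify_candidates(
    m, list(v), list(structure(matrix(0, 768, 3),
                               class = c("text_embedding", "matrix"))))
  m_bypass <- build_cmbsformer(tiny_cf(with_text = FALSE))
  # copy shared weights so only the fusion path differs
  shared <- c("conv1", "bn1", "conv2", "bn2", "conv3", "bn3", "tok_proj",
              "blocks", "head_ln", "head")
  for (nm in shared) {
    ps <- collect_params(m[[nm]]); pb <- collect_params(m_bypass[[nm]])
    for (i in seq_along(ps)) pb[[i]]$value <- ps[[i]]$value
  }
  m_bypass$pos1$value <- m$pos1$value
  m_bypass$pos2$value <- m$pos2$value
  m_bypass$cls_token$value <- m$cls_token$value
  bypass <- classify_candidates(m_bypass, list(v))
  expect_false(isTRUE(all.equal(with_zero_text$probability,
                                bypass$probability)))
  expect_error(classify_candidates(m, list(v)), "requires")
})

test_that("probabilities are valid, deterministic and variant-B is larger", {
  m <- build_cmbsformer(tiny_cf())
  vs <- list(rand_volume(5), rand_volume(6))
  ts <- list(rand_text(5), rand_text(6))
  r1 <- classify_candidates(m, vs, ts)
  expect_true(all(r1$probability >= 0 & r1$probability <= 1))
  expect_identical(r1$label, as.integer(r1$probability >= 0.5))
  r2 <- classify_candidates(m, vs, ts)
  expect_identical(r1$probability, r2$probability)
  pS <- n_params(build_cmbsformer(cf_config("S", embed_channels = 32L)))
  pB <- n_params(build_cmbsformer(cf_config("B", embed_channels = 32L)))
  expect_gt(pB, pS)
})

test_that("batch composition does not leak between candidates", {
  m <- build_cmbsformer(tiny_cf(with_text = FALSE))
  v1 <- rand_volume(7); v2 <- rand_volume(8); v3 <- rand_volume(9)
  alone <- classify_candidates(m, list(v1))$probability
  grouped <- classify_candidates(m, list(v3, v1, v2))$probability[2]
  expect_equal(alone, grouped, tolerance = 1e-9)
})

test_that("training smoke runs, rejects single-class sets, traces TPR/TNR", {
  set.seed(30)
  vols <- lapply(1:16, rand_volume)
  labs <- rep(c(1L, 0L), 8)
  m <- build_cmbsformer(tiny_cf(with_text = FALSE))
  expect_error(train_classifier(m, vols, rep(1L, 16)), "single class")
  r <- train_classifier(m, vols, labs, epochs = 1L, seed = 2L,
                        batch_size = 8L)
  expect_true(is.finite(r$trace$loss))
  expect_true(all(c("val_tpr", "val_tnr") %in% names(r$trace)))
})
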