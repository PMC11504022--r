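# The synthetic SWI/phase phantom generator.

tiny_spec <- function(image_side = 96L, ...) {
  phantom_spec(slices_per_patient = 6L, image_side = image_side,
               cmb_diameter = c(4, 20), ...)
}

test_that("generation is byte-identical for a fixed seed", {
  spec <- tiny_spec()
  a <- generate_patient(spec, 77)
  b <- generate_patient(spec, 77)
  expect_identical(record_checksum(a), record_checksum(b))
  c <- generate_patient(spec, 78)
  expect_false(identical(record_checksum(a), record_checksum(c)))
})

test_that("a zero-CMB configuration yields an empty ground truth", {
  spec <- tiny_spec(positive_fraction = 0, calc_rate = 0.5, vessel_rate = 0.5)
  rec <- generate_patient(spec, 5)
  expect_false(rec$has_cmbs)
  expect_identical(sum(vapply(rec$gt_boxes, nrow, 0L)), 0L)
  expect_true(all(rec$objects$type != "cmb"))
})

test_that("an implanted 8 px CMB leaves a 7-10 px ground-truth footprint", {
  # render the blob profile directly and measure the rasterized footprint
  prof <- blob_profile(64, 32, 32, 4, 100)
  bx <- footprint_box(prof, 100)
  expect_gte(bx["x2"] - bx["x1"], 7)
  expect_lte(bx["x2"] - bx["x1"], 10)
  expect_gte(bx["y2"] - bx["y1"], 7)
  expect_lte(bx["y2"] - bx["y1"], 10)
})

test_that("CMB boxes contain a hypointense core and phase contrast obeys sign rules", {
  spec <- tiny_spec(image_side = 128L, cmb_mean = 2, calc_rate = 1.5,
                    positive_fraction = 1)
  found_cmb <- 0L; found_calc <- 0L
  for (seed in 1:6) {
    rec <- generate_patient(spec, seed)
    side <- nrow(rec$swi[[1]])
    for (s in seq_along(rec$swi)) {
      g <- rec$gt_boxes[[s]]
      if (!nrow(g)) next
      for (k in seq_len(nrow(g))) {
        xs <- max(1, floor(g[k, 1]) + 1):min(side, ceiling(g[k, 3]))
        ys <- max(1, floor(g[k, 2]) + 1):min(side, ceiling(g[k, 4]))
        inside <- rec$swi[[s]][ys, xs]
        # local minimum well below the background level
        expect_lt(min(inside), mean(rec$swi[[s]]) - 30)
      }
    }
    # phase-contrast rule per object type at its center slice
    for (i in seq_len(nrow(rec$objects))) {
      o <- rec$objects[i, ]
      if (o$type == "vessel") next
      s <- (o$slice_from + o$slice_to) %/% 2
      xs <- max(1, round(o$cx - o$r)):min(side, round(o$cx + o$r))
      ys <- max(1, round(o$cy - o$r)):min(side, round(o$cy + o$r))
      ph_in <- mean(rec$phase[[s]][ys, xs])
      ph_all <- mean(rec$phase[[s]])
      if (o$type == "calc") {
        expect_gt(ph_in, ph_all)
        found_calc <- found_calc + 1L
      } else {
        expect_lt(ph_in, ph_all)
        found_cmb <- found_cmb + 1L
      }
    }
  }
  expect_gt(found_cmb, 0L)
  expect_gt(found_calc, 0L)
})

test_that("SWI appearance alone does not separate CMBs from calcifications", {
  # same size and depth draws for both classes: their SWI summary
  # statistics overlap (no deterministic separator on min intensity)
  spec <- tiny_spec(image_side = 128L, cmb_mean = 2, calc_rate = 2,
                    positive_fraction = 1, metadata_effect = 1.5)
  mins_cmb <- c(); mins_calc <- c()
  for (seed in 1:10) {
    rec <- generate_patient(spec, seed)
    side <- nrow(rec$swi[[1]])
    for (i in seq_len(nrow(rec$objects))) {
      o <- rec$objects[i, ]
      if (o$type == "vessel") next
      s <- (o$slice_from + o$slice_to) %/% 2
      xs <- max(1, round(o$cx - o$r)):min(side, round(o$cx + o$r))
      ys <- max(1, round(o$cy - o$r)):min(side, round(o$cy + o$r))
      v <- min(rec$swi[[s]][ys, xs])
      if (o$type == "cmb") mins_cmb <- c(mins_cmb, v)
      else mins_calc <- c(mins_calc, v)
    }
  }
  expect_gt(length(mins_cmb), 3)
  expect_gt(length(mins_calc), 3)
  # the supports overlap: neither class dominates the other
  expect_lt(min(mins_calc), max(mins_cmb))
  expect_lt(min(mins_cmb), max(mins_calc))
})

test_that("datasets split disjointly and regenerate exactly from the manifest", {
  spec <- tiny_spec()
  ds <- generate_dataset(spec, 10, seed = 3)
  expect_length(c(ds$train, ds$val, ds$test), 10)
  expect_length(ds$manifest$patients, 10)
  ids <- vapply(c(ds$train, ds$val, ds$test), `[[`, "", "patient_id")
  expect_identical(anyDuplicated(ids), 0L)
  ds2 <- regenerate_from_manifest(ds$manifest)
  for (i in seq_along(ds$manifest$patients)) {
    expect_identical(ds$manifest$patients[[i]]$checksum,
                     ds2$manifest$patients[[i]]$checksum)
  }
})

test_that("the requested positive fraction is honored on average", {
  spec <- tiny_spec(positive_fraction = 0.37)
  ds <- generate_dataset(spec, 40, seed = 8)
  pos <- sum(vapply(ds$manifest$patients, `[[`, TRUE, "has_cmbs"))
  # binomial(40, 0.37): central 99.9% range
  expect_gte(pos, 5)
  expect_lte(pos, 27)
})

test_that("metadata modulates the calcification rate in the stated direction", {
  spec <- tiny_spec(image_side = 128L, metadata_effect = 1.5, calc_rate = 1.2)
  n_f <- 0; n_m <- 0; k_f <- 0; k_m <- 0
  for (seed in 1:120) {
    rec <- generate_patient(spec, seed)
    ncalc <- sum(rec$objects$type == "calc")
    if (rec$meta$gender == "female") { n_f <- n_f + 1; k_f <- k_f + ncalc }
    else { n_m <- n_m + 1; k_m <- k_m + ncalc }
  }
  expect_gt(k_f / n_f, k_m / n_m)  # female patients carry more mimics
})
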