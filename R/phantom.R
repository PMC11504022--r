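#' Synthetic SWI/phase phantom specification
#'
#' Defines the statistical structure of the generated patients. A phantom
#' patient is a stack of SWI slices plus a matching stack of phase slices
#' over a noisy background with a smooth bias field, into which three
#' object families are implanted inside a circular "brain" region:
#'
#' * **CMBs** -- round hypointense blobs spanning 1--3 consecutive slices,
#'   dark in both SWI and phase (paramagnetic blood products). Only these
#'   receive ground-truth boxes.
#' * **Calcification mimics** -- drawn from the *same* SWI size/contrast
#'   distribution as CMBs (so SWI appearance alone cannot separate them)
#'   but *hyperintense* in the phase image, with variable contrast
#'   magnitude (diamagnetic calcium).
#' * **Vessel mimics** -- elongated hypointense tubes persisting over at
#'   least 4 consecutive slices, dark in both modalities.
#'
#' Patient metadata follows the cohort structure of a screening
#' population: about 37% of patients carry CMBs, CMB-positive patients
#' are older on average (mean 65 vs 58 years), and the calcification-mimic
#' rate depends on age and gender with strength `metadata_effect`, making
#' the demographic text prompts genuinely informative for mimic rejection.
#'
#' @param slices_per_patient Slices per stack (default 16; a full-scale
#'   emulation would use 130).
#' @param image_side Square slice side in pixels (default 256).
#' @param cmb_mean Mean CMB count for a CMB-positive patient (count is
#'   `1 + Poisson(cmb_mean - 1)` so positives always carry at least one).
#' @param cmb_diameter Length-2 range of CMB/mimic diameters in pixels.
#' @param calc_rate,vessel_rate Baseline Poisson means of mimic counts per
#'   patient.
#' @param positive_fraction Probability a patient has CMBs.
#' @param metadata_effect Strength with which age and gender modulate the
#'   calcification rate (0 = no link between metadata and mimics).
#' @param background_mean,noise_sd,bias_amp Background gray level, pixel
#'   noise SD and bias-field amplitude (0--255 scale) for SWI.
#' @param cmb_depth Range of SWI attenuation depths for CMBs and mimics.
#' @param phase_bias_amp Bias-field amplitude of the phase image.
#' @param seed Default seed used when none is passed to the generators.
#' @return A list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(slices_per_patient = 16L, image_side = 256L,
                         cmb_mean = 3, cmb_diameter = c(4, 32),
                         calc_rate = 1.2, vessel_rate = 1.0,
                         positive_fraction = 0.37, metadata_effect = 1.5,
                         background_mean = 150, noise_sd = 6, bias_amp = 15,
                         cmb_depth = c(70, 120), phase_bias_amp = 4,
                         seed = 1L) {
  stopifnot(slices_per_patient >= 1L, image_side >= 32L,
            length(cmb_diameter) == 2L, cmb_diameter[1] >= 2,
            cmb_diameter[2] <= image_side / 4,
            positive_fraction >= 0, positive_fraction <= 1,
            metadata_effect >= 0, calc_rate >= 0, vessel_rate >= 0)
  structure(list(slices_per_patient = as.integer(slices_per_patient),
                 image_side = as.integer(image_side), cmb_mean = cmb_mean,
                 cmb_diameter = cmb_diameter, calc_rate = calc_rate,
                 vessel_rate = vessel_rate,
                 positive_fraction = positive_fraction,
                 metadata_effect = metadata_effect,
                 background_mean = background_mean, noise_sd = noise_sd,
                 bias_amp = bias_amp, cmb_depth = cmb_depth,
                 phase_bias_amp = phase_bias_amp, seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# smooth low-frequency bias field via bilinear upsampling of a coarse grid
bias_field <- function(side, amp, grid = 4L) {
  coarse <- matrix(stats::rnorm(grid * grid), grid, grid)
  U <- interp_matrix(side, side, grid, "bilinear")
  matrix(U %*% as.vector(coarse), side, side) * amp
}

# additive smooth disk profile: amp at center, sigmoid edge at radius r
blob_profile <- function(side, cx, cy, r, amp, edge = 0.7) {
  xs <- seq_len(side)
  dx2 <- outer(rep(1, side), (xs - cx)^2)
  dy2 <- outer((xs - cy)^2, rep(1, side))
  d <- sqrt(dx2 + dy2)
  amp * stats::plogis((r - d) / edge)
}

# capsule (line segment with rounded caps) profile for vessels
capsule_profile <- function(side, x1, y1, x2, y2, halfw, amp, edge = 0.7) {
  xs <- seq_len(side)
  px <- outer(rep(1, side), xs)
  py <- outer(xs, rep(1, side))
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- pmin(pmax(((px - x1) * vx + (py - y1) * vy) / len2, 0), 1)
  d <- sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
  amp * stats::plogis((halfw - d) / edge)
}

# bounding box of the rendered footprint (pixels above 30% of peak depth)
footprint_box <- function(profile, amp) {
  mask <- which(profile > 0.3 * amp, arr.ind = TRUE)
  if (!nrow(mask)) return(NULL)
  # arr.ind: row = y, col = x; convert to 0-based continuous box edges
  c(x1 = min(mask[, 2]) - 1, y1 = min(mask[, 1]) - 1,
    x2 = max(mask[, 2]), y2 = max(mask[, 1]))
}

#' Generate one phantom patient
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; byte-identical output for identical inputs.
#' @return A list of class `"patient_record"` with fields `patient_id`,
#'   `swi` and `phase` (lists of `side x side` integer matrices on the
#'   0--255 scale), `meta` ([patient_meta()]), `gt_boxes` (per-slice
#'   `n x 4` box matrices; CMBs only -- the evaluation truth),
#'   `cand_boxes` (per-slice boxes of *all* implanted objects; the
#'   candidate-region targets a stage-1 screening detector trains on,
#'   since mimics are by construction indistinguishable from CMBs in SWI
#'   alone) and `objects` (the full truth table including mimics).
#' @export
generate_patient <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    side <- spec$image_side
    S <- spec$slices_per_patient
    has_cmbs <- stats::runif(1) < spec$positive_fraction
    gender <- if (stats::runif(1) < 0.6) "male" else "female"
    age_mu <- if (has_cmbs) 65 else 58
    age <- round(pmin(pmax(stats::rnorm(1, age_mu, 9), 30), 90))
    meta <- patient_meta(sprintf("phantom-%08d", seed %% 1e8), gender, age)

    n_cmb <- if (has_cmbs) 1L + stats::rpois(1, max(spec$cmb_mean - 1, 0)) else 0L
    # calcification odds rise with age and are higher in female patients
    # (centered so the cohort mean stays near calc_rate)
    lambda_calc <- min(6, spec$calc_rate *
      exp(spec$metadata_effect *
            ((age - 60) / 20 + 0.8 * ((gender == "female") - 0.5))))
    n_calc <- stats::rpois(1, lambda_calc)
    n_ves <- stats::rpois(1, spec$vessel_rate)

    # draw object geometry first, then place largest-first so big objects
    # are not crowded out by earlier small ones
    plans <- list()
    plan_blob <- function(type) {
      d <- stats::runif(1, spec$cmb_diameter[1], spec$cmb_diameter[2])
      r <- d / 2
      span <- sample(1:3, 1)
      s0 <- sample(seq_len(S), 1)
      s_from <- max(1L, s0 - (span - 1L) %/% 2L)
      depth <- stats::runif(1, spec$cmb_depth[1], spec$cmb_depth[2])
      # phase contrast is reliable in sign but variable in magnitude
      # (partial-volume effects make the phase cue noisy for small
      # lesions), so phase is informative but not sufficient on its own
      phase_amp <- if (type == "calc") (6 + stats::rexp(1, 1 / 14)) else
        -(6 + stats::rexp(1, 1 / 14))
      plans[[length(plans) + 1L]] <<- list(
        type = type, r = r, reach = r + 3,
        slice_from = s_from, slice_to = min(S, s_from + span - 1L),
        depth = depth, phase_amp = phase_amp)
    }
    for (i in seq_len(n_cmb)) plan_blob("cmb")
    for (i in seq_len(n_calc)) plan_blob("calc")
    for (i in seq_len(n_ves)) {
      len <- stats::runif(1, 0.08 * side, 0.18 * side)
      halfw <- stats::runif(1, 1.5, 2.5)
      ang <- stats::runif(1, 0, pi)
      span <- sample(4:min(8, S), 1)
      s_from <- sample(seq_len(max(S - span + 1L, 1L)), 1)
      plans[[length(plans) + 1L]] <- list(
        type = "vessel", r = len / 2, reach = len / 2 + halfw + 3,
        slice_from = s_from, slice_to = min(S, s_from + span - 1L),
        depth = stats::runif(1, spec$cmb_depth[1], spec$cmb_depth[2]) * 0.8,
        phase_amp = -(6 + stats::rexp(1, 1 / 14)),
        len = len, halfw = halfw, ang = ang)
    }

    # objects may share in-plane position only if their slice ranges are
    # disjoint by more than one slice (crops take i-1..i+1)
    placed <- matrix(numeric(0), 0, 5)   # cx, cy, reach, s_from, s_to
    place <- function(reach, s_from, s_to) {
      for (try in 1:500) {
        a <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * max(0.42 * side - reach - 2, 1)
        cx <- side / 2 + rad * cos(a)
        cy <- side / 2 + rad * sin(a)
        ok <- TRUE
        if (nrow(placed)) {
          margin <- if (try <= 250) 4 else 0   # relax separation when crowded
          close <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) <=
            placed[, 3] + reach + margin
          slice_clash <- placed[, 4] <= s_to + 1 & placed[, 5] >= s_from - 1
          ok <- !any(close & slice_clash)
        }
        if (ok) {
          placed <<- rbind(placed, c(cx, cy, reach, s_from, s_to))
          return(c(cx, cy))
        }
      }
      NULL
    }
    objects <- NULL
    ordered <- plans[order(-vapply(plans, `[[`, 0, "reach"))]
    for (layout_try in 1:10) {                # deterministic layout retries
      placed <- matrix(numeric(0), 0, 5)
      objects <- list()
      failed <- FALSE
      for (pl in ordered) {
        ctr <- place(pl$reach, pl$slice_from, pl$slice_to)
        if (is.null(ctr)) { failed <- TRUE; break }
        pl$cx <- ctr[1]; pl$cy <- ctr[2]
        objects[[length(objects) + 1L]] <- pl
      }
      if (!failed) break
      if (layout_try == 10) {
        stop(sprintf(paste0("infeasible phantom geometry: %d objects (max ",
                            "reach %.1f px) do not fit a %d px slice after ",
                            "10 layout attempts; reduce object rates or ",
                            "sizes, or enlarge image_side"),
                     length(ordered), max(vapply(ordered, `[[`, 0, "reach")),
                     side))
      }
    }

    swi_bias <- bias_field(side, spec$bias_amp)
    phase_bias <- bias_field(side, spec$phase_bias_amp)
    swi <- vector("list", S)
    phase <- vector("list", S)
    empty_boxes <- matrix(numeric(0), 0, 4,
                          dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
    gt_boxes <- rep(list(empty_boxes), S)     # CMBs only (evaluation truth)
    cand_boxes <- rep(list(empty_boxes), S)   # all objects (stage-1 targets)

    profiles <- lapply(objects, function(o) {
      if (o$type == "vessel") {
        dx <- cos(o$ang) * o$len / 2; dy <- sin(o$ang) * o$len / 2
        capsule_profile(side, o$cx - dx, o$cy - dy, o$cx + dx, o$cy + dy,
                        o$halfw, 1)
      } else {
        blob_profile(side, o$cx, o$cy, o$r, 1)
      }
    })

    for (s in seq_len(S)) {
      sw <- spec$background_mean + swi_bias +
        matrix(stats::rnorm(side * side, 0, spec$noise_sd), side, side)
      ph <- 128 + phase_bias +
        matrix(stats::rnorm(side * side, 0, spec$noise_sd * 0.8), side, side)
      for (i in seq_along(objects)) {
        o <- objects[[i]]
        if (s < o$slice_from || s > o$slice_to) next
        # partial-volume taper on first/last slice of multi-slice objects
        taper <- if ((s == o$slice_from || s == o$slice_to) &&
                     o$slice_to > o$slice_from) 0.55 else 1
        sw <- sw - profiles[[i]] * o$depth * taper
        ph <- ph + profiles[[i]] * o$phase_amp * taper
        bx <- footprint_box(profiles[[i]] * o$depth * taper, o$depth * taper)
        if (!is.null(bx)) {
          cand_boxes[[s]] <- rbind(cand_boxes[[s]], bx)
          if (o$type == "cmb") gt_boxes[[s]] <- rbind(gt_boxes[[s]], bx)
        }
      }
      swi[[s]] <- round(pmin(pmax(sw, 0), 255))
      phase[[s]] <- round(pmin(pmax(ph, 0), 255))
    }

    obj_df <- if (length(objects)) {
      data.frame(type = vapply(objects, `[[`, "", "type"),
                 cx = vapply(objects, `[[`, 0, "cx"),
                 cy = vapply(objects, `[[`, 0, "cy"),
                 r = vapply(objects, `[[`, 0, "r"),
                 slice_from = vapply(objects, `[[`, 0L, "slice_from"),
                 slice_to = vapply(objects, `[[`, 0L, "slice_to"),
                 depth = vapply(objects, `[[`, 0, "depth"),
                 phase_amp = vapply(objects, `[[`, 0, "phase_amp"))
    } else {
      data.frame(type = character(), cx = numeric(), cy = numeric(),
                 r = numeric(), slice_from = integer(), slice_to = integer(),
                 depth = numeric(), phase_amp = numeric())
    }
    structure(list(patient_id = meta$patient_id, swi = swi, phase = phase,
                   meta = meta, gt_boxes = gt_boxes, cand_boxes = cand_boxes,
                   objects = obj_df, has_cmbs = has_cmbs, seed = seed),
              class = "patient_record")
  })
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient %s: %d slices %dx%d, %s, age %d, %d CMB boxes, %d mimics>\n",
              x$patient_id, length(x$swi), nrow(x$swi[[1]]), ncol(x$swi[[1]]),
              x$meta$gender, x$meta$age,
              sum(vapply(x$gt_boxes, nrow, 0L)),
              sum(x$objects$type != "cmb")))
  invisible(x)
}

# deterministic md5 checksum of a record (serialization version pinned)
record_checksum <- function(rec) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(rec, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Generate a split phantom dataset with a reproducibility manifest
#'
#' Patient seeds are derived deterministically from `seed`; the manifest
#' records every parameter and per-patient seed, so
#' [regenerate_from_manifest()] rebuilds the identical dataset.
#'
#' @param spec A [phantom_spec()].
#' @param n Number of patients (>= 3).
#' @param seed Integer master seed.
#' @param split Train/val/test fractions (must sum to 1).
#' @return List with `train`, `val`, `test` (lists of patient records) and
#'   `manifest`.
#' @export
generate_dataset <- function(spec, n, seed = spec$seed,
                             split = c(train = 0.6, val = 0.2, test = 0.2)) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 3, abs(sum(split) - 1) < 1e-9)
  pseeds <- (as.numeric(seed) * 100003 + seq_len(n) * 7919) %% 2147483629 + 1
  records <- lapply(pseeds, function(s) generate_patient(spec, as.integer(s)))
  n_train <- max(1L, floor(n * split[1]))
  n_val <- max(1L, floor(n * split[2]))
  assignment <- c(rep("train", n_train), rep("val", n_val),
                  rep("test", n - n_train - n_val))
  manifest <- list(
    spec = unclass(spec), n = n, seed = seed, split = as.list(split),
    patients = lapply(seq_len(n), function(i) list(
      patient_id = records[[i]]$patient_id, seed = as.integer(pseeds[i]),
      split = assignment[i], has_cmbs = records[[i]]$has_cmbs,
      n_boxes = sum(vapply(records[[i]]$gt_boxes, nrow, 0L)),
      checksum = record_checksum(records[[i]]))))
  list(train = records[assignment == "train"],
       val = records[assignment == "val"],
       test = records[assignment == "test"],
       manifest = manifest)
}

#' Rebuild a phantom dataset from its manifest alone
#' @param manifest The `manifest` element of a [generate_dataset()] result.
#' @return The same structure as [generate_dataset()].
#' @export
regenerate_from_manifest <- function(manifest) {
  spec <- do.call(phantom_spec, manifest$spec)
  generate_dataset(spec, manifest$n, manifest$seed,
                   split = unlist(manifest$split))
}

# Truth-table candidate sampler for classifier training: one candidate per
# implanted object (CMBs labelled 1, mimics 0), centered on the object at
# its middle slice with a small seeded jitter emulating detector placement.
truth_candidates <- function(record, jitter = 1.5, seed = 1L) {
  with_seed(seed, {
    obj <- record$objects
    out <- vector("list", nrow(obj))
    side <- nrow(record$swi[[1]])
    for (i in seq_len(nrow(obj))) {
      o <- obj[i, ]
      s_mid <- (o$slice_from + o$slice_to) %/% 2L
      cx <- o$cx + stats::rnorm(1, 0, jitter)
      cy <- o$cy + stats::rnorm(1, 0, jitter)
      half <- if (o$type == "vessel") o$r else o$r + 1.5
      bx <- c(max(cx - half, 0), max(cy - half, 0),
              min(cx + half, side), min(cy + half, side))
      out[[i]] <- list(
        label = as.integer(o$type == "cmb"),
        type = o$type,
        slice_index = s_mid - 1L,                 # 0-based
        box = box(bx[1], bx[2], bx[3], bx[4]),
        prev_hit = o$slice_from < s_mid,
        next_hit = o$slice_to > s_mid)
    }
    out
  })
}
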