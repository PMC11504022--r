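# Readers and writers for the on-disk formats shared by the pipeline:
# PNG slice directories, NIfTI volumes, YOLO-txt and COCO-JSON labels,
# CSV metadata, YAML configs and JSON-lines logs.
#
# Conventions: slice indices are 0-based everywhere in code; PNG file
# names carry 1-based, zero-padded human labels ("slice_0001.png" is
# slice index 0). Boxes are (x1, y1, x2, y2) internally; conversion to
# COCO [x, y, w, h] and normalized YOLO (class cx cy w h) happens only at
# the I/O boundary.

#' Read an ordered slice stack
#'
#' Slices are returned as matrices linearly normalized to the 0--255
#' range (16-bit or float inputs are rescaled; the applied scale and
#' offset are recorded as attributes `scale` and `offset`). Color inputs
#' are converted to grayscale by channel averaging. Use
#' [stack_to_input()] to obtain the three-channel array consumed by the
#' detector.
#'
#' @param path Directory of PNG slices (sorted by zero-padded index) or a
#'   NIfTI file.
#' @param format `"png_dir"` or `"nifti"`. A NIfTI volume of shape
#'   `(X, Y, Z)` yields `Z` slices of `(X, Y)` (axis 3 is the slice axis).
#' @return List of `H x W` matrices on the 0--255 scale.
#' @export
read_stack <- function(path, format = c("png_dir", "nifti")) {
  format <- match.arg(format)
  if (format == "png_dir") {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
      round(img * 255)
    })
  } else {
    vol <- RNifti::readNifti(path)
    v <- as.array(vol)
    if (length(dim(v)) != 3L) stop("expected a 3D NIfTI volume")
    rng <- range(v)
    scale <- if (diff(rng) > 0) 255 / diff(rng) else 1
    slices <- lapply(seq_len(dim(v)[3]), function(z) {
      m <- (v[, , z] - rng[1]) * scale
      attr(m, "scale") <- scale
      attr(m, "offset") <- rng[1]
      round(m)
    })
  }
  dims <- vapply(slices, function(s) paste(dim(s), collapse = "x"), character(1))
  if (length(unique(dims)) != 1L) {
    stop("mixed slice resolutions within one stack: ",
         paste(unique(dims), collapse = ", "))
  }
  slices
}

#' Write a slice stack
#'
#' @param stack List of `H x W` matrices (0--255).
#' @param path Output directory (PNG) or file (NIfTI).
#' @param format `"png_dir"` or `"nifti"`.
#' @export
write_stack <- function(stack, path, format = c("png_dir", "nifti")) {
  format <- match.arg(format)
  if (format == "png_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(stack)) {
      png::writePNG(pmin(pmax(stack[[i]], 0), 255) / 255,
                    file.path(path, sprintf("slice_%04d.png", i)))
    }
  } else {
    d <- dim(stack[[1]])
    vol <- array(0, c(d[1], d[2], length(stack)))
    for (i in seq_along(stack)) vol[, , i] <- stack[[i]]
    RNifti::writeNifti(RNifti::asNifti(vol), path)
  }
  invisible(path)
}

#' Replicate a grayscale stack to the three-channel detector input
#'
#' @param stack List of `H x W` matrices (0--255).
#' @return List of `H x W x 3` arrays with values scaled to \[0, 1\].
#' @export
stack_to_input <- function(stack) {
  lapply(stack, function(m) {
    a <- array(rep(m / 255, 3L), c(dim(m), 3L))
    a
  })
}

#' Convert label records between YOLO and COCO conventions
#'
#' In-memory conversion; records are a data frame with columns `image_id`,
#' `class_id` and either corner boxes (`x1,y1,x2,y2`), COCO boxes
#' (`x,y,w,h`) or normalized YOLO fields (`cx,cy,w,h` in \[0, 1\]).
#' Round trips differ by less than 1e-6 in normalized units.
#'
#' @param records Label data frame.
#' @param from,to One of `"xyxy"`, `"coco"`, `"yolo"`.
#' @param image_size `c(width, height)`; required for the YOLO convention.
#' @param strict If `TRUE`, out-of-bounds or degenerate boxes are an
#'   error; otherwise they are clipped with a warning.
#' @return Converted data frame.
#' @export
convert_labels <- function(records, from = c("xyxy", "coco", "yolo"),
                           to = c("xyxy", "coco", "yolo"),
                           image_size = NULL, strict = FALSE) {
  from <- match.arg(from); to <- match.arg(to)
  need_size <- "yolo" %in% c(from, to)
  if (need_size && (is.null(image_size) || length(image_size) != 2L)) {
    stop("image_size = c(width, height) is required for the YOLO convention")
  }
  m <- switch(from,
    xyxy = as.matrix(records[, c("x1", "y1", "x2", "y2")]),
    coco = xywh_to_box(as.matrix(records[, c("x", "y", "w", "h")])),
    yolo = yolo_to_box(as.matrix(records[, c("cx", "cy", "w", "h")]),
                       image_size[1], image_size[2]))
  if (any(m[, 3] <= m[, 1]) || any(m[, 4] <= m[, 2])) {
    stop("degenerate box (zero or negative extent) in label records")
  }
  if (!is.null(image_size)) {
    oob <- m[, 1] < 0 | m[, 2] < 0 | m[, 3] > image_size[1] |
      m[, 4] > image_size[2]
    if (any(oob)) {
      if (strict) stop(sum(oob), " out-of-bounds box(es) in strict mode")
      warning(sum(oob), " out-of-bounds box(es) clipped to the image")
      m[, 1] <- pmax(m[, 1], 0); m[, 2] <- pmax(m[, 2], 0)
      m[, 3] <- pmin(m[, 3], image_size[1]); m[, 4] <- pmin(m[, 4], image_size[2])
    }
  }
  out <- data.frame(image_id = records$image_id,
                    class_id = records$class_id %||% 0L)
  conv <- switch(to,
    xyxy = {colnames(m) <- c("x1", "y1", "x2", "y2"); m},
    coco = box_to_xywh(m),
    yolo = box_to_yolo(m, image_size[1], image_size[2]))
  cbind(out, as.data.frame(conv))
}

#' Read / write YOLO-format label text files
#'
#' One line per box: `class cx cy w h`, normalized to the image size.
#' @param file Path to the `.txt` file.
#' @param image_size `c(width, height)`.
#' @return Data frame with `class_id` and corner coordinates.
#' @export
read_yolo_txt <- function(file, image_size) {
  if (!file.exists(file) || !length(readLines(file, warn = FALSE))) {
    return(data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric()))
  }
  m <- as.matrix(utils::read.table(file))
  b <- yolo_to_box(m[, 2:5, drop = FALSE], image_size[1], image_size[2])
  data.frame(class_id = as.integer(m[, 1]), b)
}

#' @rdname read_yolo_txt
#' @param boxes `n x 4` matrix of corner boxes.
#' @param class_id Class indices (default 0).
#' @export
write_yolo_txt <- function(boxes, file, image_size, class_id = 0L) {
  m <- as_box_matrix(boxes)
  y <- box_to_yolo(m, image_size[1], image_size[2])
  lines <- sprintf("%d %.10g %.10g %.10g %.10g",
                   rep_len(class_id, nrow(m)), y[, 1], y[, 2], y[, 3], y[, 4])
  writeLines(lines, file)
  invisible(file)
}

#' Write detections as COCO-style JSON with a slice_index field
#'
#' @param detections Data frame with `slice_index`, corner coordinates and
#'   `score`.
#' @param file Output path.
#' @export
write_detections_json <- function(detections, file) {
  ann <- lapply(seq_len(nrow(detections)), function(i) {
    d <- detections[i, ]
    list(id = i, slice_index = as.integer(d$slice_index),
         category_id = 0L,
         bbox = as.numeric(box_to_xywh(c(d$x1, d$y1, d$x2, d$y2))),
         score = as.numeric(d$score))
  })
  jsonlite::write_json(list(annotations = ann), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_detections_json
#' @export
read_detections_json <- function(file) {
  j <- jsonlite::read_json(file)
  ann <- j$annotations
  if (!length(ann)) {
    return(data.frame(slice_index = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(), score = numeric()))
  }
  do.call(rbind, lapply(ann, function(a) {
    b <- as.numeric(unlist(a$bbox))
    data.frame(slice_index = a$slice_index, x1 = b[1], y1 = b[2],
               x2 = b[1] + b[3], y2 = b[2] + b[4], score = a$score)
  }))
}

#' Read / write YAML run configuration
#' @param path YAML file path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config Named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Deterministic hash of a configuration list
#'
#' Canonical JSON (sorted keys, fixed precision) hashed with MD5; used to
#' stamp logs and reports so identical configurations are recognizable.
#' @param config Named list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = 10), f)
  unname(tools::md5sum(f))
}

#' Append a structured record to a JSON-lines log
#' @param path Log file path.
#' @param record Named list (seeds and config hashes included by callers).
#' @export
log_jsonl <- function(path, record) {
  con <- file(path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = 10), con)
  invisible(path)
}
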