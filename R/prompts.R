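#' Patient metadata
#'
#' @param patient_id Identifier string.
#' @param gender `"male"` or `"female"` (the two tokens the prompt
#'   template accepts).
#' @param age Integer years in \[0, 130\].
#' @param history Optional character vector of medical-history items
#'   (e.g. "hypertension").
#' @param lifestyle Optional character vector of lifestyle items
#'   (e.g. "smoking").
#' @return A list of class `"patient_meta"`.
#' @export
patient_meta <- function(patient_id, gender, age, history = NULL,
                         lifestyle = NULL) {
  if (missing(gender) || length(gender) != 1L || is.na(gender) ||
      !gender %in% c("male", "female")) {
    stop("gender must be \"male\" or \"female\" (no silent default)")
  }
  if (missing(age) || length(age) != 1L || is.na(age) || age < 0 || age > 130) {
    stop("age must be a single value in [0, 130] (no silent default)")
  }
  structure(list(patient_id = as.character(patient_id), gender = gender,
                 age = as.integer(age),
                 history = as.character(history %||% character()),
                 lifestyle = as.character(lifestyle %||% character())),
            class = "patient_meta")
}

round_half_up <- function(x) floor(x + 0.5)

#' Build the text prompts for one candidate region
#'
#' Instantiates the fixed prompt templates: a demographic statement, a
#' box-geometry statement ("length" is the box height and "width" the box
#' width, both rounded half-up to integer pixels), and one slice-adjacency
#' statement each for the previous and next slice. Optional
#' history/lifestyle items are appended one statement per item. The order
#' is fixed: demographics, geometry, adjacency, then history/lifestyle.
#'
#' @param meta A [patient_meta()].
#' @param box The candidate [box()].
#' @param prev_hit,next_hit Logical: was a detection present at the same
#'   position on the previous/next slice?
#' @return A list of class `"prompt_set"` with element `statements`.
#' @examples
#' build_prompts(patient_meta("p1", "female", 55), box(10, 20, 16, 28),
#'               prev_hit = TRUE, next_hit = FALSE)
#' @export
build_prompts <- function(meta, box, prev_hit, next_hit) {
  stopifnot(inherits(meta, "patient_meta"),
            is.logical(prev_hit), is.logical(next_hit),
            !is.na(prev_hit), !is.na(next_hit))
  m <- validate_boxes(as_box_matrix(box))
  len <- round_half_up(m[1, 4] - m[1, 2])   # height
  wid <- round_half_up(m[1, 3] - m[1, 1])   # width
  yn <- function(f) if (f) "yes" else "no"
  st <- c(
    sprintf("This is a %s patient with %d years old.", meta$gender, meta$age),
    sprintf("Target length and width are %d and %d pixels.", len, wid),
    sprintf("The detection status of the previous frame at the same position is %s.",
            yn(prev_hit)),
    sprintf("The detection status of the next frame at the same position is %s.",
            yn(next_hit)))
  extra <- c(meta$history, meta$lifestyle)
  extra <- extra[nzchar(extra)]
  if (length(extra)) {
    st <- c(st, sprintf("The patient has a history of %s.", extra))
  }
  structure(list(statements = st), class = "prompt_set")
}

#' @export
print.prompt_set <- function(x, ...) {
  cat(sprintf("<prompt set, %d statements>\n", length(x$statements)))
  for (s in x$statements) cat("  ", s, "\n", sep = "")
  invisible(x)
}

# 32-bit-safe polynomial string hash (deterministic across platforms):
# h <- (h * 31 + byte) mod (2^31 - 1). 31 * (2^31 - 1) + 255 < 2^53, so
# double arithmetic is exact.
poly_hash <- function(s, mult = 31, mod = 2147483647) {
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * mult + b) %% mod
  h
}

#' Deterministic feature-hashing sentence encoder
#'
#' A network-free encoder mapping any statement to a fixed 768-dimensional
#' vector so the full pipeline builds and tests offline. Each lowercase
#' word token and each character trigram of the statement is hashed
#' (32-bit-safe polynomial hashes, byte-level identical across platforms
#' for a fixed seed) onto several of the 768 dimensions with a hashed
#' sign, and the resulting sparse count vector is L2-normalized. Distinct
#' statements collide with probability close to zero; a pretrained
#' sentence encoder can be supplied anywhere this encoder is accepted,
#' as any `function(string) -> numeric(768)`.
#'
#' @param seed Integer mixed into every hash.
#' @param dim Output width (768 to match the classifier's text branch).
#' @return A function mapping one character string to a numeric vector.
#' @export
hash_encoder <- function(seed = 0L, dim = 768L) {
  force(seed); force(dim)
  enc <- function(s) {
    stopifnot(is.character(s), length(s) == 1L)
    low <- tolower(s)
    words <- strsplit(gsub("[^a-z0-9]+", " ", low), " +")[[1]]
    words <- words[nzchar(words)]
    chars <- strsplit(low, "")[[1]]
    tris <- if (length(chars) >= 3) {
      vapply(seq_len(length(chars) - 2L),
             function(i) paste(chars[i:(i + 2L)], collapse = ""), character(1))
    } else character()
    v <- numeric(dim)
    for (tok in c(words, paste0("#", tris))) {
      key <- paste0(seed, ":", tok)
      h1 <- poly_hash(key, 31)
      h2 <- poly_hash(key, 37)
      h3 <- poly_hash(key, 41)
      sgn <- if (h3 %% 2 == 0) 1 else -1
      v[(h1 %% dim) + 1L] <- v[(h1 %% dim) + 1L] + sgn
      v[(h2 %% dim) + 1L] <- v[(h2 %% dim) + 1L] - sgn
    }
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  }
  attr(enc, "encoder_name") <- sprintf("hash-%d-%d", seed, dim)
  enc
}

#' Encode a prompt set into a text embedding matrix
#'
#' @param p A [build_prompts()] result.
#' @param encoder A `function(string) -> numeric(768)`; defaults to the
#'   offline [hash_encoder()].
#' @return A `768 x n` matrix of class `"text_embedding"` whose column `i`
#'   encodes statement `i`; attribute `encoder_name` records the encoder.
#' @export
encode_prompts <- function(p, encoder = hash_encoder()) {
  stopifnot(inherits(p, "prompt_set"), length(p$statements) >= 1L)
  cols <- lapply(p$statements, encoder)
  widths <- lengths(cols)
  if (any(widths != 768L)) {
    stop(sprintf("encoder produced width %d; the text branch requires 768",
                 widths[which(widths != 768L)[1]]))
  }
  m <- do.call(cbind, cols)
  if (any(!is.finite(m))) stop("encoder produced non-finite values")
  structure(m, class = c("text_embedding", class(m)),
            encoder_name = attr(encoder, "encoder_name") %||% "custom")
}

#' Read patient metadata from CSV
#'
#' Expected columns: `patient_id`, `gender`, `age`, and optional `history`
#' and `lifestyle` (semicolon-separated lists).
#' @param path CSV file path.
#' @return List of [patient_meta()].
#' @export
read_patient_meta_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_items <- function(s) {
    if (is.null(s) || is.na(s) || !nzchar(s)) character() else
      trimws(strsplit(s, ";")[[1]])
  }
  lapply(seq_len(nrow(df)), function(i) {
    patient_meta(df$patient_id[i], df$gender[i], df$age[i],
                 history = if ("history" %in% names(df))
                   split_items(df$history[i]) else NULL,
                 lifestyle = if ("lifestyle" %in% names(df))
                   split_items(df$lifestyle[i]) else NULL)
  })
}
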