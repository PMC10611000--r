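#' Emotion label sets
#'
#' The package works with Ekman's six basic emotions plus neutrality. The
#' fixed seven-emotion ordering (alphabetical: anger, disgust, fear, happy,
#' neutral, sad, surprise) is used everywhere a label vector or a report
#' column order matters, so that binary label vectors, classifier heads and
#' agreement tables always line up.
#'
#' @return `emotion_levels()` returns the seven emotion names in canonical
#'   order; `basic_emotions()` returns the six basic emotions (no neutral).
#' @examples
#' emotion_levels()
#' basic_emotions()
#' @export
emotion_levels <- function() {
  c("anger", "disgust", "fear", "happy", "neutral", "sad", "surprise")
}

#' @rdname emotion_levels
#' @export
basic_emotions <- function() {
  setdiff(emotion_levels(), "neutral")
}

check_emotion <- function(emotion, allow_neutral = TRUE) {
  pool <- if (allow_neutral) emotion_levels() else basic_emotions()
  if (length(emotion) != 1L || !emotion %in% pool) {
    stop("unknown emotion: ", paste(emotion, collapse = ", "), call. = FALSE)
  }
  emotion
}

# Evaluate `expr` under a fixed RNG seed and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed, staying well inside
# 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + i * 104729) %% 2147483629)
}

# Split a semicolon-joined label string into a character vector.
split_labels <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_labels <- function(labels) {
  vapply(labels, function(v) paste(v, collapse = ";"), character(1))
}
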