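#' Construct a landmark frame
#'
#' One face observation: an ordered set of 2-D landmark points in
#' image-pixel coordinates (y grows downward, the usual image convention).
#' With 68 points the ordering is assumed to follow the standard 68-point
#' facial annotation scheme.
#'
#' @param points numeric N x 2 matrix (columns x, y).
#' @param space `"raw"` (pixel coordinates) or `"normalized"`.
#' @return an object of class `landmark_frame`.
#' @export
landmark_frame <- function(points, space = c("raw", "normalized")) {
  space <- match.arg(space)
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 1) {
    stop("points must be an N x 2 matrix", call. = FALSE)
  }
  if (!all(is.finite(points))) stop("non-finite landmark coordinates", call. = FALSE)
  colnames(points) <- c("x", "y")
  structure(list(points = points, space = space), class = "landmark_frame")
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat("Landmark frame:", nrow(x$points), "points (", x$space, "space )\n")
  invisible(x)
}

#' Anchor landmarks used for normalization
#'
#' Four expression-stable anatomical points drive the coordinate
#' normalization: the left and right lateral face points, the nasal center
#' (top of the nose bridge, between the eyes) and the subnasal center (base
#' of the nose). The defaults are the standard 68-point scheme positions
#' — jaw extremes and nose-bridge points — expressed as 1-based R indices
#' (scheme points 0, 16, 27, 33).
#'
#' @param left,right,nasal,subnasal 1-based landmark indices.
#' @return an object of class `anchor_set`.
#' @export
anchor_set <- function(left = 1L, right = 17L, nasal = 28L, subnasal = 34L) {
  idx <- c(left = left, right = right, nasal = nasal, subnasal = subnasal)
  if (anyDuplicated(idx) || any(idx < 1)) {
    stop("anchors must be four distinct positive indices", call. = FALSE)
  }
  structure(as.integer(idx), names = names(idx), class = "anchor_set")
}

check_anchors <- function(frame, anchors) {
  if (any(anchors > nrow(frame$points))) {
    stop("anchor index out of range for this frame", call. = FALSE)
  }
  anchors
}

#' Anchor distances of a raw frame
#'
#' The three normalization denominators: the horizontal (x-axis) distances
#' from the nasal center to the left and right lateral anchors, and the
#' vertical (y-axis) distance from the nasal center to the subnasal center.
#' Distances are axis-aligned coordinate differences, not Euclidean norms.
#'
#' @param frame a raw `landmark_frame`.
#' @param anchors an `anchor_set`.
#' @return named numeric vector `c(d_left, d_right, d_vert)`, all strictly
#'   positive.
#' @export
anchor_distances <- function(frame, anchors = anchor_set()) {
  stopifnot(inherits(frame, "landmark_frame"))
  if (frame$space != "raw") stop("frame must be in raw space", call. = FALSE)
  check_anchors(frame, anchors)
  p <- frame$points
  d_left <- p[anchors[["nasal"]], "x"] - p[anchors[["left"]], "x"]
  d_right <- p[anchors[["right"]], "x"] - p[anchors[["nasal"]], "x"]
  d_vert <- abs(p[anchors[["subnasal"]], "y"] - p[anchors[["nasal"]], "y"])
  d <- c(d_left = unname(d_left), d_right = unname(d_right),
         d_vert = unname(d_vert))
  if (any(d <= 0)) stop("degenerate anchors", call. = FALSE)
  d
}

#' Normalize a landmark frame with the anchor distances
#'
#' Coordinates are re-expressed relative to the nasal center: x offsets of
#' points left of the nasal center are divided by the left anchor distance,
#' x offsets of the remaining points by the right anchor distance, and all y
#' offsets by the vertical nose distance. The result is translation-free and
#' invariant to independent positive axis scalings, which removes both head
#' position in the camera frame and overall face size.
#'
#' @inheritParams anchor_distances
#' @return the normalized `landmark_frame`.
#' @examples
#' pts <- rbind(c(6, 10), c(16, 10), c(10, 10), c(10, 12), c(8, 14))
#' fr <- landmark_frame(pts)
#' a <- anchor_set(left = 1, right = 2, nasal = 3, subnasal = 4)
#' normalize_frame(fr, a)$points[5, ]  # (-0.5, 2.0)
#' @export
normalize_frame <- function(frame, anchors = anchor_set()) {
  d <- anchor_distances(frame, anchors)
  p <- frame$points
  nc <- p[anchors[["nasal"]], ]
  dx <- p[, "x"] - nc[["x"]]
  dy <- p[, "y"] - nc[["y"]]
  x_new <- ifelse(dx < 0, dx / d[["d_left"]], dx / d[["d_right"]])
  y_new <- dy / d[["d_vert"]]
  landmark_frame(cbind(x_new, y_new), space = "normalized")
}

#' Default action-unit landmark subset
#'
#' The 22 landmarks retained as features, chosen to cover the facial
#' muscles most responsible for expression: four brow points, six eye
#' points (corners plus upper lids), the two nose wings, and ten mouth
#' points (corners, outer lip contour and inner lip midpoints). Indices are
#' 1-based positions in the standard 68-point scheme and can be overridden
#' wherever a subset is accepted.
#'
#' @return sorted integer vector of 22 landmark indices.
#' @export
default_feature_subset <- function() {
  c(
    20L, 22L, 23L, 25L,                               # brows
    37L, 39L, 40L, 43L, 44L, 46L,                     # eye corners + upper lids
    32L, 36L,                                         # nose wings
    49L, 51L, 52L, 53L, 55L, 57L, 58L, 59L, 63L, 67L  # mouth
  )
}

#' Extract the feature vector of a normalized frame
#'
#' Concatenates the (x, y) coordinates of the subset landmarks in subset
#' order: with the default 22-point subset this yields the 44-value feature
#' vector used by the classifiers.
#'
#' @param frame a normalized `landmark_frame`.
#' @param subset integer vector of 1-based landmark indices.
#' @return numeric vector of length `2 * length(subset)`, laid out
#'   `x_i, y_i` per landmark.
#' @export
select_features <- function(frame, subset = default_feature_subset()) {
  stopifnot(inherits(frame, "landmark_frame"))
  if (frame$space != "normalized") stop("normalize first", call. = FALSE)
  if (any(subset < 1 | subset > nrow(frame$points))) {
    stop("subset index out of range", call. = FALSE)
  }
  as.vector(t(frame$points[subset, , drop = FALSE]))
}

#' Landmark frame table I/O and batch feature extraction
#'
#' A frame table is a data.frame with a `sample_id` column followed by the
#' interleaved coordinate columns `x0, y0, ..., x67, y67` (0-based names,
#' matching the conventional annotation numbering). `frames_to_features()`
#' normalizes every row and extracts its feature vector, returning a
#' data.frame `sample_id, f0..f43`.
#'
#' @param frames a frame table.
#' @param path file path.
#' @param i row number.
#' @param anchors an `anchor_set`.
#' @param subset feature subset (1-based indices).
#' @name frame_io
#' @export
write_frames <- function(frames, path) {
  utils::write.csv(frames, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname frame_io
#' @export
read_frames <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sample_id = "character"))
}

#' @rdname frame_io
#' @export
frame_from_row <- function(frames, i, space = c("raw", "normalized")) {
  coord_cols <- grep("^[xy][0-9]+$", names(frames), value = TRUE)
  v <- as.numeric(frames[i, coord_cols])
  landmark_frame(matrix(v, ncol = 2, byrow = TRUE), space = match.arg(space))
}

#' @rdname frame_io
#' @param space coordinate space flag for the rows being read.
#' @export
frames_to_features <- function(frames, anchors = anchor_set(),
                               subset = default_feature_subset()) {
  feats <- t(vapply(seq_len(nrow(frames)), function(i) {
    fr <- normalize_frame(frame_from_row(frames, i), anchors)
    select_features(fr, subset)
  }, numeric(2 * length(subset))))
  out <- data.frame(sample_id = frames$sample_id, feats,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", paste0("f", seq_len(2 * length(subset)) - 1))
  out
}
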