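#' Extract facial landmarks from an image via a pluggable detector
#'
#' Bridges raw face images to [landmark_frame()] rows without making the
#' core pipeline depend on any computer-vision stack. A detector is a list
#' with a `detect(image)` function returning a list of candidate 68 x 2
#' coordinate matrices (columns x, y; image pixel coordinates, origin
#' top-left, y downward), one per face found. Face detection, HOG features
#' and alignment are the detector's concern — this package only adapts its
#' output.
#'
#' With no face the status is `"no_face"`; with several faces the largest
#' bounding box wins and the status is `"multiple_faces"`; a missing or
#' failing detector yields status `"error"` (a capability condition, never
#' a crash), so the coordinate pipeline still runs where no detector is
#' installed.
#'
#' @param image a numeric matrix or array of pixel values (e.g. from
#'   [read_face_image()]).
#' @param detector a detector handle, e.g. [stub_detector()].
#' @param participant_id,frame_index metadata for the resulting frame.
#' @return list of class `extraction_result` with `frame` (a
#'   [landmark_frame()] or `NULL`) and `status` (one of `"ok"`,
#'   `"no_face"`, `"multiple_faces"`, `"error"`).
#' @export
extract_landmarks <- function(image, detector, participant_id = "p1",
                              frame_index = 0L) {
  result <- function(frame, status) {
    structure(list(frame = frame, status = status),
              class = "extraction_result")
  }
  if (missing(detector) || is.null(detector) ||
      !is.function(detector$detect)) {
    return(result(NULL, "error"))
  }
  faces <- tryCatch(detector$detect(image), error = function(e) e)
  if (inherits(faces, "error")) return(result(NULL, "error"))
  if (!length(faces)) return(result(NULL, "no_face"))
  bad <- !vapply(faces, function(f) is.matrix(f) && all(dim(f) == c(68, 2)),
                 TRUE)
  if (any(bad)) return(result(NULL, "error"))
  # several candidates: the largest bounding box is taken to be the
  # operator facing the camera, and extraction still succeeds
  area <- vapply(faces, function(f) {
    prod(apply(f, 2, function(col) diff(range(col))))
  }, 0)
  f <- faces[[which.max(area)]]
  result(landmark_frame(c(f[, 1], f[, 2]), participant_id, frame_index), "ok")
}

#' A stub detector returning planted coordinates
#'
#' Test double standing in for a real 68-landmark detector: always
#' "detects" the supplied coordinate sets regardless of the image content.
#'
#' @param ... one or more 68 x 2 coordinate matrices (zero for a detector
#'   that never finds a face).
#' @return a detector handle usable with [extract_landmarks()].
#' @export
stub_detector <- function(...) {
  faces <- list(...)
  list(detect = function(image) faces)
}

#' Read a PNG face image as a grayscale pixel matrix
#'
#' Requires the optional \pkg{png} package; raises a capability error when
#' it is unavailable.
#'
#' @param path PNG file path.
#' @return numeric matrix of gray levels in `[0, 1]`.
#' @export
read_face_image <- function(path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_mfd("the 'png' package is required to decode images",
              "mfd_capability_error")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}
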