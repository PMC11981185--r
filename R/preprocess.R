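#' Flag outliers with the three-sigma rule
#'
#' A value is an outlier when it lies strictly outside the band
#' `mean +/- k_sigma * sigma`, with mean and population standard deviation
#' computed over the finite entries of the sequence. Values exactly on the
#' band edge are kept; non-finite entries (missing / corrupt coordinates)
#' are always flagged.
#'
#' @param values numeric sequence (one feature over time).
#' @param k_sigma band half-width in standard deviations (default 3).
#' @return logical vector, `TRUE` where the cell is an outlier.
#' @export
#' @examples
#' detect_outliers(c(1, 2, 3))        # all inside the band
#' detect_outliers(c(rep(0, 10), 50)) # the planted spike is flagged
detect_outliers <- function(values, k_sigma = 3) {
  fin <- is.finite(values)
  if (sum(fin) < 2) {
    abort_mfd("need at least 2 finite values to estimate the outlier band",
              "mfd_degenerate_error")
  }
  m <- mean(values[fin])
  s <- sqrt(mean((values[fin] - m)^2)) # population sigma
  flags <- !fin
  flags[fin] <- abs(values[fin] - m) > k_sigma * s
  flags
}

#' Repair flagged cells by neighbour-mean imputation
#'
#' Each flagged cell is replaced by the mean of the nearest preceding and
#' nearest following unflagged values; at the boundary (no neighbour on one
#' side) the single nearest unflagged value is used. Unflagged cells are
#' never modified, so the operation is idempotent on its output.
#'
#' @param values numeric sequence.
#' @param mask logical flags, e.g. from [detect_outliers()].
#' @return repaired numeric sequence.
#' @export
#' @examples
#' impute_outliers(c(1, 99, 3), c(FALSE, TRUE, FALSE)) # -> 1 2 3
impute_outliers <- function(values, mask) {
  stopifnot(length(values) == length(mask))
  if (all(mask)) {
    abort_mfd("entire sequence flagged; nothing to impute from",
              "mfd_degenerate_error")
  }
  good <- which(!mask)
  out <- values
  for (i in which(mask)) {
    prev <- good[good < i]
    nxt <- good[good > i]
    out[i] <- if (length(prev) && length(nxt)) {
      (values[prev[length(prev)]] + values[nxt[1]]) / 2
    } else if (length(prev)) {
      values[prev[length(prev)]]
    } else {
      values[nxt[1]]
    }
  }
  out
}

#' Convert absolute landmark positions to relative ones
#'
#' Subtracts the 68-point centroid from every landmark and divides by the
#' frame's bounding-box diagonal, making the representation exactly
#' invariant to translation and uniform scaling of the face within the
#' image, so detection is unaffected by where the participant sits relative
#' to the camera.
#'
#' @param frame a [landmark_frame()], or a numeric vector of 136 finite
#'   coordinates (`x1..x68, y1..y68`).
#' @return object of the same kind with relativised coordinates.
#' @export
relativize_frame <- function(frame) {
  if (inherits(frame, "landmark_frame")) {
    frame$coords <- stats::setNames(relativize_coords(frame$coords),
                                    feature_names_all())
    return(frame)
  }
  relativize_coords(frame)
}

relativize_coords <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 136 || !all(is.finite(v))) {
    abort_mfd("relativisation requires 136 finite coordinates",
              "mfd_validation_error")
  }
  xs <- v[1:68]; ys <- v[69:136]
  diag <- sqrt(diff(range(xs))^2 + diff(range(ys))^2)
  if (diag == 0) {
    abort_mfd("all landmarks coincide; bounding-box diagonal is zero",
              "mfd_degenerate_error")
  }
  c((xs - mean(xs)) / diag, (ys - mean(ys)) / diag)
}

#' Fit a per-feature min-max normalisation
#'
#' Records each feature's minimum and maximum over the fitting rows. The
#' transform maps a value `m` to `(m - min) / (max - min)`, so fitted rows
#' land in `[0, 1]`; rows transformed later (validation / test) may fall
#' outside that interval and are deliberately not clipped. Fit on training
#' rows only to avoid information leaking from evaluation data.
#'
#' @param x numeric matrix (rows = frames, columns = features).
#' @return an object of class `minmax_state` with elements `min`, `max`
#'   (named per feature) and `l` (number of fitting rows).
#' @export
fit_minmax <- function(x) {
  x <- as.matrix(x)
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  bad <- which(hi == lo | !is.finite(lo) | !is.finite(hi))
  if (length(bad)) {
    abort_mfd(sprintf("degenerate feature(s) with zero range: %s",
                      paste(utils::head(colnames(x)[bad] %||% bad, 5),
                            collapse = ", ")),
              "mfd_degenerate_error")
  }
  structure(list(min = lo, max = hi, l = nrow(x)), class = "minmax_state")
}

#' Apply (or invert) a fitted min-max normalisation
#' @param state a `minmax_state` from [fit_minmax()].
#' @param x numeric matrix with the same columns as the fitting matrix.
#' @return transformed matrix.
#' @export
apply_minmax <- function(state, x) {
  x <- as.matrix(x)
  stopifnot(inherits(state, "minmax_state"), ncol(x) == length(state$min))
  sweep(sweep(x, 2, state$min, "-"), 2, state$max - state$min, "/")
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(state, x) {
  x <- as.matrix(x)
  stopifnot(inherits(state, "minmax_state"), ncol(x) == length(state$min))
  sweep(sweep(x, 2, state$max - state$min, "*"), 2, state$min, "+")
}

#' Serialise / restore a normalisation state as JSON
#' @param state a `minmax_state`.
#' @param path JSON file path.
#' @return `path` (write) or a `minmax_state` (read).
#' @export
write_minmax_json <- function(state, path) {
  jsonlite::write_json(list(min = unclass(state$min), max = unclass(state$max),
                            l = state$l),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_minmax_json
#' @export
read_minmax_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = o$min, max = o$max, l = o$l), class = "minmax_state")
}

#' Preprocess a landmark dataset
#'
#' Runs the repair-and-normalise chain in order: per participant and per
#' feature, three-sigma outlier detection then neighbour-mean imputation
#' (occlusion statistics are session-specific, so the band is estimated
#' within each participant's own recording); then per-frame relativisation;
#' then min-max normalisation fitted on `fit_index` rows only and applied
#' to all rows.
#'
#' @param ds an `mfd_data` dataset.
#' @param fit_index integer row indices used to fit the normalisation
#'   (default: all rows).
#' @param k_sigma outlier band half-width (default 3).
#' @param relativize,normalize logical stage toggles (defaults `TRUE`).
#' @return list with elements `dataset` (repaired `mfd_data`), `state`
#'   (`minmax_state` or `NULL`) and `mask` (n x 136 logical outlier mask).
#' @export
preprocess_mfd <- function(ds, fit_index = NULL, k_sigma = 3,
                           relativize = TRUE, normalize = TRUE) {
  coords <- landmark_matrix(ds)
  n <- nrow(coords)
  fit_index <- fit_index %||% seq_len(n)
  mask <- matrix(FALSE, n, 136, dimnames = list(NULL, colnames(coords)))
  for (p in unique(ds$participant_id)) {
    rows <- which(ds$participant_id == p)
    for (j in seq_len(136)) {
      fl <- detect_outliers(coords[rows, j], k_sigma = k_sigma)
      mask[rows, j] <- fl
      if (any(fl)) coords[rows, j] <- impute_outliers(coords[rows, j], fl)
    }
  }
  if (relativize) {
    coords <- t(apply(coords, 1, relativize_coords))
    colnames(coords) <- feature_names_all()
  }
  state <- NULL
  if (normalize) {
    state <- fit_minmax(coords[fit_index, , drop = FALSE])
    coords <- apply_minmax(state, coords)
  }
  out <- mfd_data(coords, ds$kss, ds$participant_id, ds$frame_index,
                  provenance = attr(ds, "provenance") %||% "")
  list(dataset = out, state = state, mask = mask)
}
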