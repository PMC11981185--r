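#' Construct a labeled landmark dataset
#'
#' The unit every pipeline stage consumes and produces: one row per face
#' observation with a participant id, a frame index, the fatigue label
#' (`kss`, integer 1-5 on the simplified Karolinska Sleepiness Scale) and the
#' 136 landmark coordinates `x1..x68, y1..y68` in pixel units. Coordinates
#' may be `NA` (missing / occluded) only before preprocessing.
#'
#' @param coords numeric matrix (n x 136) or data.frame of coordinates, with
#'   columns in storage order (see [feature_names_all()]).
#' @param kss integer vector of fatigue levels in 1..5.
#' @param participant_id character vector of non-empty participant ids
#'   (recycled if length 1).
#' @param frame_index non-negative integer frame counters (default `0..n-1`
#'   within the supplied order).
#' @param provenance free-text metadata (file path, generator config, ...).
#' @return an object of class `mfd_data` (a data.frame).
#' @export
mfd_data <- function(coords, kss, participant_id = "p1",
                     frame_index = NULL, provenance = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 136) {
    abort_mfd(sprintf("expected 136 coordinate columns, got %d", ncol(coords)),
              "mfd_format_error")
  }
  n <- nrow(coords)
  kss <- as.integer(kss)
  if (length(kss) != n) {
    abort_mfd("labels and frames differ in length", "mfd_validation_error")
  }
  if (n > 0 && (anyNA(kss) || any(kss < 1L | kss > 5L))) {
    abort_mfd("fatigue labels must be integers in 1..5", "mfd_validation_error")
  }
  participant_id <- rep_len(as.character(participant_id), max(n, 0L))
  if (n > 0 && any(!nzchar(participant_id))) {
    abort_mfd("participant ids must be non-empty", "mfd_validation_error")
  }
  if (is.null(frame_index)) {
    frame_index <- integer(n)
    for (p in unique(participant_id)) {
      idx <- which(participant_id == p)
      frame_index[idx] <- seq_along(idx) - 1L
    }
  }
  frame_index <- as.integer(frame_index)
  if (n > 0 && any(frame_index < 0L)) {
    abort_mfd("frame_index must be non-negative", "mfd_validation_error")
  }
  colnames(coords) <- feature_names_all()
  df <- data.frame(participant_id = participant_id,
                   frame_index = frame_index,
                   kss = kss, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(coords))
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("mfd_data", "data.frame"))
}

#' Extract the n x 136 coordinate matrix from a dataset
#' @param ds an `mfd_data` object.
#' @return numeric matrix with columns named `x1..x68, y1..y68`.
#' @export
landmark_matrix <- function(ds) {
  as.matrix(ds[, feature_names_all(), drop = FALSE])
}

#' Construct a single landmark frame
#'
#' @param coords numeric vector of 136 coordinates (`x1..x68`, `y1..y68`).
#' @param participant_id participant identifier.
#' @param frame_index non-negative integer.
#' @return a named list of class `landmark_frame`.
#' @export
landmark_frame <- function(coords, participant_id = "p1", frame_index = 0L) {
  coords <- as.numeric(coords)
  if (length(coords) != 136) {
    abort_mfd("a landmark frame holds exactly 136 coordinates",
              "mfd_format_error")
  }
  structure(list(participant_id = as.character(participant_id),
                 frame_index = as.integer(frame_index),
                 coords = stats::setNames(coords, feature_names_all())),
            class = "landmark_frame")
}

#' Read a labeled landmark dataset from CSV
#'
#' Expects the header `participant_id,frame_index,kss,x1,...,x68,y1,...,y68`
#' (any column order is accepted; all columns must be present and no extra
#' coordinate columns may appear). Empty coordinate cells are read as `NA`,
#' the missing-value sentinel repaired later by preprocessing.
#'
#' @param path CSV file path.
#' @return an `mfd_data` object preserving the file's row order.
#' @export
read_mfd_csv <- function(path) {
  if (!file.exists(path)) {
    abort_mfd(sprintf("file not found: %s", path), "mfd_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("participant_id", "frame_index", "kss", feature_names_all())
  missing <- setdiff(need, names(df))
  extra_coord <- setdiff(grep("^[xy][0-9]+$", names(df), value = TRUE),
                         feature_names_all())
  if (length(missing) || length(extra_coord)) {
    abort_mfd(sprintf(
      "bad dataset header: %d missing column(s) [%s], %d unexpected coordinate column(s)",
      length(missing), paste(utils::head(missing, 4), collapse = ", "),
      length(extra_coord)), "mfd_format_error")
  }
  coords <- as.matrix(df[, feature_names_all(), drop = FALSE])
  storage.mode(coords) <- "double"
  kss <- suppressWarnings(as.numeric(df$kss))
  if (nrow(df) > 0 && (anyNA(kss) || any(kss != round(kss)) ||
                       any(kss < 1 | kss > 5))) {
    abort_mfd("kss labels must be integers in 1..5", "mfd_validation_error")
  }
  mfd_data(coords, as.integer(kss), df$participant_id,
           as.integer(df$frame_index), provenance = path)
}

#' Write a labeled landmark dataset to CSV
#'
#' Writes the canonical header order
#' `participant_id,frame_index,kss,x1,...,x68,y1,...,y68`, UTF-8, "." decimal.
#' Non-finite coordinates are written as empty cells so that the file
#' round-trips through [read_mfd_csv()].
#'
#' @param ds an `mfd_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mfd_csv <- function(ds, path) {
  out <- ds[, c("participant_id", "frame_index", "kss", feature_names_all()),
            drop = FALSE]
  class(out) <- "data.frame"
  if (nrow(out) > 0) {
    cm <- as.matrix(out[, feature_names_all(), drop = FALSE])
    cm[!is.finite(cm)] <- NA_real_
    out[, feature_names_all()] <- cm
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_mfd(sprintf("cannot write %s", path), "mfd_io_error")
  invisible(path)
}

#' Bundled reference tables
#'
#' Accessors for the small plain-text reference tables shipped with the
#' package: the original 10-level and simplified 5-level sleepiness scales
#' (the 5-level table also carries the pilot study's per-class sample sizes),
#' the published retained-feature list in compact range notation, the
#' published baseline hyperparameters, the published threshold-selection
#' cross-validation scores, and the published comparison means (accuracy in
#' percent, signed deviation) of the five detection methods.
#'
#' @param which one of `"kss10"`, `"kss5"`, `"retained"`, `"hyperparameters"`,
#'   `"threshold_scores"`, `"comparison"`.
#' @return a data.frame, a character vector of range tokens (`"retained"`),
#'   or a named list (`"hyperparameters"`).
#' @export
#' @examples
#' length(expand_feature_ranges(mfd_reference("retained")))
mfd_reference <- function(which = c("kss10", "kss5", "retained",
                                    "hyperparameters", "threshold_scores",
                                    "comparison")) {
  which <- match.arg(which)
  f <- function(name) system.file("extdata", name, package = "drnrf",
                                  mustWork = TRUE)
  switch(which,
    kss10 = utils::read.delim(f("kss_scale_original.tsv")),
    kss5 = utils::read.delim(f("kss_scale_simplified.tsv")),
    retained = {
      lines <- readLines(f("retained_features.txt"))
      lines <- lines[!grepl("^\\s*(#|$)", lines)]
      sub("^[^:]*:\\s*", "", lines)
    },
    hyperparameters = yaml::read_yaml(f("reference_hyperparameters.yaml")),
    threshold_scores = utils::read.delim(f("threshold_cv_scores.tsv")),
    comparison = utils::read.delim(f("reference_comparison.tsv"))
  )
}
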