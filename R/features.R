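#' Landmark feature naming conventions
#'
#' A frame of 68 facial landmarks is stored as a 136-long coordinate vector,
#' ordered `x1..x68` then `y1..y68` (iBUG 68-point numbering, 1-based).
#' Feature ids are the strings `"x<k>"` / `"y<k>"`; [feature_column()] maps a
#' feature id to its column in the 136-wide coordinate matrix and
#' [feature_name()] inverts the mapping.
#'
#' @name landmark-features
NULL

#' All 136 landmark feature names in storage order
#' @return character vector `c("x1", ..., "x68", "y1", ..., "y68")`.
#' @export
feature_names_all <- function() {
  c(paste0("x", 1:68), paste0("y", 1:68))
}

parse_feature <- function(id) {
  ok <- grepl("^[xy][0-9]+$", id)
  if (!all(ok)) {
    abort_mfd(sprintf("malformed feature id(s): %s",
                      paste(id[!ok], collapse = ", ")), "mfd_format_error")
  }
  axis <- substr(id, 1, 1)
  landmark <- as.integer(substring(id, 2))
  if (any(landmark < 1 | landmark > 68)) {
    abort_mfd("landmark index outside 1..68", "mfd_validation_error")
  }
  list(axis = axis, landmark = landmark)
}

#' Map feature ids to coordinate-matrix columns
#'
#' `x<k>` maps to column `k`, `y<k>` to column `68 + k` (1-based). The mapping
#' is a bijection over the 136 columns.
#'
#' @param id character vector of feature ids, e.g. `"x31"`.
#' @return integer column indices.
#' @export
#' @examples
#' feature_column(c("x1", "y1", "y68"))
feature_column <- function(id) {
  p <- parse_feature(id)
  ifelse(p$axis == "x", p$landmark, 68L + p$landmark)
}

#' Map coordinate-matrix columns to feature ids
#' @param col integer column indices in `1..136`.
#' @return character feature ids.
#' @export
feature_name <- function(col) {
  col <- as.integer(col)
  if (any(col < 1 | col > 136)) {
    abort_mfd("column index outside 1..136", "mfd_validation_error")
  }
  ifelse(col <= 68, paste0("x", col), paste0("y", col - 68L))
}

#' Expand compact feature-range notation
#'
#' Retained-feature lists are written compactly as single ids (`"y34"`) or
#' inclusive ranges with a tilde (`"x1 ~ x17"`), the convention used to report
#' which of the 136 coordinates survive stability selection. Each input
#' string may hold several comma-separated tokens. Both endpoints of a range
#' are included; duplicates collapse.
#'
#' @param spec character vector of tokens or comma-separated token lists.
#' @return character vector of unique feature ids, ordered by storage column.
#' @export
#' @examples
#' expand_feature_ranges(c("x1 ~ x3", "y34"))
expand_feature_ranges <- function(spec) {
  tokens <- unlist(strsplit(spec, ",", fixed = TRUE), use.names = FALSE)
  tokens <- trimws(tokens)
  tokens <- tokens[nzchar(tokens)]
  out <- character(0)
  for (tok in tokens) {
    if (grepl("~", tok, fixed = TRUE)) {
      ends <- trimws(strsplit(tok, "~", fixed = TRUE)[[1]])
      if (length(ends) != 2) {
        abort_mfd(sprintf("malformed range token '%s'", tok), "mfd_format_error")
      }
      a <- parse_feature(ends[1]); b <- parse_feature(ends[2])
      if (a$axis != b$axis) {
        abort_mfd(sprintf("axis mismatch in range '%s'", tok), "mfd_validation_error")
      }
      if (a$landmark > b$landmark) {
        abort_mfd(sprintf("decreasing range '%s'", tok), "mfd_validation_error")
      }
      out <- c(out, paste0(a$axis, seq(a$landmark, b$landmark)))
    } else {
      parse_feature(tok)
      out <- c(out, tok)
    }
  }
  out <- unique(out)
  out[order(feature_column(out))]
}
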