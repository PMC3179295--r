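# Shared internal helpers: rounding, landmark-table validation, and conversion
# between the tidy landmark representation and the n x 2k coordinate matrix
# used by the numerical core.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed report values here follow
#' the half-up convention (so 1.375 -> 1.38, 4.55 -> 4.6).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(1.375, 4.545), 2)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

landmark_cols <- c("subject_id", "point", "x", "y")

# Validate a tidy landmark table: required columns, no missing coordinates,
# k >= 3 and identical across subjects. Returns k invisibly.
validate_landmarks <- function(landmarks, min_k = 3) {
  missing_cols <- setdiff(landmark_cols, names(landmarks))
  if (length(missing_cols) > 0) {
    abort(
      paste0(
        "Landmark table is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "hipshape_error_landmark_columns"
    )
  }
  bad <- !is.finite(landmarks$x) | !is.finite(landmarks$y)
  if (any(bad)) {
    abort(
      paste0(
        "Missing or non-finite coordinates for subject(s): ",
        paste(unique(landmarks$subject_id[bad]), collapse = ", ")
      ),
      class = "hipshape_error_landmark_na"
    )
  }
  counts <- table(landmarks$subject_id)
  k <- as.integer(counts[[1]])
  if (length(unique(as.integer(counts))) != 1) {
    k_mode <- as.integer(names(sort(table(as.integer(counts)), decreasing = TRUE))[1])
    offenders <- names(counts)[as.integer(counts) != k_mode]
    abort(
      paste0(
        "All subjects must share the same point count (modal k = ", k_mode,
        "); offending subject(s): ", paste(offenders, collapse = ", ")
      ),
      class = "hipshape_error_mixed_k"
    )
  }
  if (k < min_k) {
    abort(
      paste0("At least ", min_k, " points per outline are required (got ", k, ")."),
      class = "hipshape_error_too_few_points"
    )
  }
  invisible(k)
}

#' Convert a tidy landmark table to a coordinate matrix
#'
#' Rows are subjects (in order of first appearance), columns interleave
#' coordinates as `x1, y1, x2, y2, ...`.
#'
#' @param landmarks Tidy landmark table with columns `subject_id`, `point`,
#'   `x`, `y`.
#' @return Numeric matrix with one row per subject and `2k` columns; row names
#'   are subject ids.
#' @export
landmark_matrix <- function(landmarks) {
  k <- validate_landmarks(landmarks)
  ids <- unique(landmarks$subject_id)
  landmarks <- dplyr::arrange(
    landmarks,
    match(.data$subject_id, ids), .data$point
  )
  m <- matrix(
    rbind(landmarks$x, landmarks$y),
    nrow = length(ids), ncol = 2L * k, byrow = TRUE
  )
  rownames(m) <- ids
  m
}

#' Convert a coordinate matrix back to a tidy landmark table
#'
#' @param m Numeric matrix (subjects x 2k, interleaved `x1, y1, ...`), or a
#'   single `2k` vector / `k x 2` matrix for one shape.
#' @param subject_id Subject ids; defaults to row names or `s1, s2, ...`.
#' @return A tibble with columns `subject_id`, `point`, `x`, `y`.
#' @export
landmark_tibble <- function(m, subject_id = NULL) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  if (ncol(m) == 2 && nrow(m) > 2) m <- matrix(t(m), nrow = 1) # one k x 2 shape
  k <- ncol(m) / 2L
  ids <- subject_id %||% rownames(m) %||% paste0("s", seq_len(nrow(m)))
  tibble::tibble(
    subject_id = rep(ids, each = k),
    point = rep(seq_len(k), times = nrow(m)),
    x = as.vector(t(m[, 2 * seq_len(k) - 1, drop = FALSE])),
    y = as.vector(t(m[, 2 * seq_len(k), drop = FALSE]))
  )
}

#' Convert between interleaved coordinate vectors and point matrices
#'
#' The numerical core stores one shape as an interleaved vector
#' `(x1, y1, x2, y2, ...)`; these helpers convert to and from the `k x 2`
#' point-matrix form.
#'
#' @param v Interleaved coordinate vector of length `2k`.
#' @param p A `k x 2` point matrix.
#' @return `points_from_vec()` a `k x 2` matrix; `vec_from_points()` a `2k`
#'   vector.
#' @export
points_from_vec <- function(v) {
  matrix(v, ncol = 2, byrow = TRUE)
}

#' @rdname points_from_vec
#' @export
vec_from_points <- function(p) {
  as.vector(t(p))
}

# Positive scalar check with a readable error.
check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a positive finite scalar."),
      class = "hipshape_error_argument"
    )
  }
  invisible(x)
}
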