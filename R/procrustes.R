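# Generalized Procrustes alignment (GPA) of 2D landmark outlines.
#
# Similarity alignment: translation, centroid-size scaling, and proper
# rotation (no reflection — the cohort contract is right-sided outlines) are
# removed; size survives only in the returned centroid sizes. In 2D the
# orthogonal-Procrustes rotation has a closed form:
#   theta = atan2(sum(a_x b_y - a_y b_x), sum(a_x b_x + a_y b_y)),
# which this implementation vectorizes across the cohort.

#' Centroid size of a landmark shape
#'
#' The square root of the summed squared distances of the points from their
#' centroid — the scale measure removed by Procrustes alignment.
#'
#' @param points A `k x 2` point matrix, an interleaved `2k` vector, or a tidy
#'   landmark table for a single subject.
#' @return Positive scalar (mm when the input is in mm).
#' @export
#' @examples
#' centroid_size(rbind(c(-.5, -.5), c(.5, -.5), c(.5, .5), c(-.5, .5)))
centroid_size <- function(points) {
  p <- as_point_matrix(points)
  centered <- sweep(p, 2, colMeans(p))
  s <- sqrt(sum(centered^2))
  if (s <= 0) {
    abort("Degenerate shape: all points identical.",
      class = "hipshape_error_degenerate"
    )
  }
  s
}

as_point_matrix <- function(points) {
  if (is.data.frame(points)) {
    if (length(unique(points$subject_id %||% "s")) > 1) {
      abort("Supply a single subject's points.", class = "hipshape_error_argument")
    }
    p <- cbind(points$x, points$y)
  } else if (is.null(dim(points))) {
    p <- points_from_vec(points)
  } else {
    p <- as.matrix(points)
  }
  if (ncol(p) != 2 || nrow(p) < 2) {
    abort("Points must form a k x 2 matrix with k >= 2.",
      class = "hipshape_error_argument"
    )
  }
  p
}

#' Optimal proper rotation between two centered shapes
#'
#' Returns the 2 x 2 rotation matrix (determinant +1; reflections are never
#' returned) minimizing the sum of squared distances from the rotated first
#' shape to the second.
#'
#' @param shape_a,shape_b Centered `k x 2` point matrices with the same k.
#' @return A 2 x 2 rotation matrix `R` such that `shape_a %*% t(R)` best fits
#'   `shape_b`.
#' @export
optimal_rotation <- function(shape_a, shape_b) {
  a <- as_point_matrix(shape_a)
  b <- as_point_matrix(shape_b)
  if (nrow(a) != nrow(b)) {
    abort("Shapes must have the same number of points.",
      class = "hipshape_error_argument"
    )
  }
  num <- sum(a[, 1] * b[, 2] - a[, 2] * b[, 1])
  den <- sum(a[, 1] * b[, 1] + a[, 2] * b[, 2])
  if (num == 0 && den == 0) {
    abort("Degenerate cross-covariance: rotation undefined.",
      class = "hipshape_error_degenerate"
    )
  }
  theta <- atan2(num, den)
  rotation_matrix(theta)
}

#' 2D rotation matrix
#'
#' @param theta Angle in radians (counter-clockwise).
#' @return A 2 x 2 rotation matrix.
#' @export
rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

# Rotate every row-shape of an n x 2k matrix onto the target 2k vector,
# using the closed-form 2D Procrustes angle per shape.
rotate_onto <- function(shapes, target) {
  k <- ncol(shapes) / 2
  xi <- 2 * seq_len(k) - 1
  yi <- xi + 1
  tx <- target[xi]
  ty <- target[yi]
  num <- shapes[, xi, drop = FALSE] %*% ty - shapes[, yi, drop = FALSE] %*% tx
  den <- shapes[, xi, drop = FALSE] %*% tx + shapes[, yi, drop = FALSE] %*% ty
  th <- atan2(num, den)
  co <- as.vector(cos(th))
  si <- as.vector(sin(th))
  out <- shapes
  out[, xi] <- co * shapes[, xi, drop = FALSE] - si * shapes[, yi, drop = FALSE]
  out[, yi] <- si * shapes[, xi, drop = FALSE] + co * shapes[, yi, drop = FALSE]
  out
}

# Center each row-shape and scale to unit centroid size.
# Returns list(shapes, sizes).
center_and_scale <- function(m) {
  k <- ncol(m) / 2
  xi <- 2 * seq_len(k) - 1
  yi <- xi + 1
  cx <- rowMeans(m[, xi, drop = FALSE])
  cy <- rowMeans(m[, yi, drop = FALSE])
  m[, xi] <- m[, xi, drop = FALSE] - cx
  m[, yi] <- m[, yi, drop = FALSE] - cy
  sizes <- sqrt(rowSums(m^2))
  if (any(sizes <= 0)) {
    abort("Degenerate shape(s) in cohort.", class = "hipshape_error_degenerate")
  }
  list(shapes = m / sizes, sizes = sizes)
}

#' Generalized Procrustes alignment of a cohort of outlines
#'
#' Iteratively centers and scales each outline to unit centroid size, rotates
#' each onto the current mean, recomputes and renormalizes the mean, and
#' repeats until the RMS change in the mean drops below `tol`. The final mean
#' (and with it every aligned shape) is rotated to best fit the first subject,
#' which pins down the otherwise-arbitrary global rotation. Optionally the
#' aligned shapes are projected orthogonally onto the tangent space at the
#' mean (standard before linear PCA on shape coordinates; on by default).
#'
#' @param landmarks Tidy landmark table (or an n x 2k coordinate matrix).
#' @param tol Convergence tolerance on the RMS change of the mean shape.
#' @param max_iter Maximum number of GPA iterations.
#' @param tangent Project aligned shapes onto the tangent space at the mean.
#' @return An object of class `gpa_alignment`: list with `shapes` (n x 2k
#'   aligned coordinates), `mean_shape` (2k, unit centroid size),
#'   `centroid_sizes` (mm), `subject_ids`, `k`, `iterations`, `converged`,
#'   `tangent`.
#' @export
gpa_align <- function(landmarks, tol = 1e-8, max_iter = 100, tangent = TRUE) {
  m <- if (is.data.frame(landmarks)) landmark_matrix(landmarks) else as.matrix(landmarks)
  n <- nrow(m)
  if (n < 2) {
    abort("GPA needs at least 2 shapes.", class = "hipshape_error_argument")
  }
  cs <- center_and_scale(m)
  shapes <- cs$shapes
  mean_shape <- shapes[1, ]
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    shapes <- rotate_onto(shapes, mean_shape)
    new_mean <- colMeans(shapes)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(paste0("GPA did not converge in ", max_iter, " iterations."))
  }
  # Pin the global rotation: rotate mean (and all shapes) to best fit shape 1.
  r <- optimal_rotation(
    points_from_vec(mean_shape),
    points_from_vec(shapes[1, ])
  )
  theta <- atan2(r[2, 1], r[1, 1])
  all_mat <- rbind(mean_shape, shapes)
  all_mat <- rotate_by(all_mat, theta)
  mean_shape <- all_mat[1, ]
  shapes <- all_mat[-1, , drop = FALSE]
  shapes <- rotate_onto(shapes, mean_shape)
  if (tangent) {
    # Orthogonal projection onto the tangent plane at the (unit-norm) mean:
    # v -> v - (<v, m> - 1) m.
    lam <- as.vector(shapes %*% mean_shape) - 1
    shapes <- shapes - outer(lam, mean_shape)
  }
  structure(
    list(
      shapes = shapes,
      mean_shape = mean_shape,
      centroid_sizes = cs$sizes,
      subject_ids = rownames(m) %||% paste0("s", seq_len(n)),
      k = ncol(m) / 2,
      iterations = iter,
      converged = converged,
      tangent = tangent
    ),
    class = "gpa_alignment"
  )
}

# Rotate all row-shapes by a single angle.
rotate_by <- function(shapes, theta) {
  k <- ncol(shapes) / 2
  xi <- 2 * seq_len(k) - 1
  yi <- xi + 1
  x <- shapes[, xi, drop = FALSE]
  y <- shapes[, yi, drop = FALSE]
  shapes[, xi] <- cos(theta) * x - sin(theta) * y
  shapes[, yi] <- sin(theta) * x + cos(theta) * y
  shapes
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat(
    "Generalized Procrustes alignment\n",
    "  shapes: ", nrow(x$shapes), " x ", x$k, " landmarks\n",
    "  iterations: ", x$iterations,
    " (", if (x$converged) "converged" else "NOT converged", ")\n",
    "  tangent projection: ", x$tangent, "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy an alignment into long landmark form
#'
#' @param x A `gpa_alignment`.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `point`, `x`, `y` (dimensionless aligned
#'   coordinates) plus `centroid_size` (mm).
#' @export
tidy.gpa_alignment <- function(x, ...) {
  out <- landmark_tibble(x$shapes, subject_id = x$subject_ids)
  out$centroid_size <- rep(x$centroid_sizes, each = x$k)
  out
}

#' @export
glance.gpa_alignment <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$shapes), k = x$k,
    iterations = x$iterations, converged = x$converged,
    tangent = x$tangent,
    mean_centroid_size = mean(x$centroid_sizes)
  )
}

#' Full Procrustes distance between two shapes
#'
#' Shapes are centered, scaled to unit centroid size, and optimally rotated
#' before the root-sum-of-squares distance is taken.
#'
#' @param shape_a,shape_b `k x 2` point matrices (or 2k vectors).
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  a <- as_point_matrix(shape_a)
  b <- as_point_matrix(shape_b)
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  r <- optimal_rotation(a, b)
  sqrt(sum((a %*% t(r) - b)^2))
}
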