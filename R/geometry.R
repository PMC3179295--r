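# Classical geometric measures from a single proximal-femur outline: femoral
# head diameter (least-squares circle fit), femoral neck width (minimal
# cross-section perpendicular to the neck axis), and femoral neck length
# (head-circle center to the intertrochanteric line).
#
# These are operational, landmark-only definitions: which outline indices
# form the head arc, the superior/inferior neck borders, the shaft and the
# trochanter landmarks is configuration (`femur_regions()`), because real
# digitization protocols differ. Measures are always computed on raw
# (unaligned, mm) landmarks, never on Procrustes-normalized shapes.

#' Landmark-index regions for geometry measures
#'
#' Index semantics follow the synthetic template's point layout (see
#' [femur_template()]); override for other digitization protocols.
#'
#' @param head Consecutive indices on the articular (head) arc.
#' @param neck_superior,neck_inferior Indices of the superior and inferior
#'   neck border segments.
#' @param shaft_medial,shaft_lateral Indices of medial and lateral shaft
#'   points; the midshaft midpoint anchoring the neck axis is the midpoint of
#'   their two centroids.
#' @param greater_troch,lesser_troch Single indices of the greater and lesser
#'   trochanter landmarks (the intertrochanteric line joins them).
#' @return A named list of index vectors.
#' @export
femur_regions <- function(head = 15:36,
                          neck_superior = 37:41,
                          neck_inferior = 10:14,
                          shaft_medial = 1:2,
                          shaft_lateral = 55:60,
                          greater_troch = 44L,
                          lesser_troch = 5L) {
  list(
    head = head, neck_superior = neck_superior, neck_inferior = neck_inferior,
    shaft_medial = shaft_medial, shaft_lateral = shaft_lateral,
    greater_troch = greater_troch, lesser_troch = lesser_troch
  )
}

#' Least-squares circle fit
#'
#' Algebraic (Kasa) fit: linear least squares for center and radius.
#'
#' @param points `k x 2` matrix of points (k >= 3, not collinear).
#' @return List with `center` (length-2), `radius`, and `rms` (RMS radial
#'   residual).
#' @export
fit_circle <- function(points) {
  p <- as_point_matrix(points)
  if (nrow(p) < 3) {
    abort("Circle fit needs at least 3 points.", class = "hipshape_error_argument")
  }
  a <- cbind(2 * p[, 1], 2 * p[, 2], 1)
  b <- p[, 1]^2 + p[, 2]^2
  if (qr(a)$rank < 3) {
    abort("Collinear points: circle fit is singular.",
      class = "hipshape_error_degenerate"
    )
  }
  sol <- qr.solve(a, b)
  center <- sol[1:2]
  radius <- sqrt(sol[3] + sum(center^2))
  resid <- sqrt(rowSums(sweep(p, 2, center)^2)) - radius
  list(center = unname(center), radius = radius, rms = sqrt(mean(resid^2)))
}

#' Femoral head diameter by circle fit
#'
#' @param points A single subject's `k x 2` point matrix (mm) or tidy
#'   landmark rows.
#' @param head_range Indices of at least 5 consecutive points on the head arc.
#' @return List with `diameter` (mm), `fit_rms` (mm), and the fitted `center`.
#' @export
head_diameter <- function(points, head_range = femur_regions()$head) {
  p <- as_point_matrix(points)
  if (length(head_range) < 5) {
    abort("`head_range` must select at least 5 points.",
      class = "hipshape_error_argument"
    )
  }
  fit <- fit_circle(p[head_range, , drop = FALSE])
  list(diameter = 2 * fit$radius, fit_rms = fit$rms, center = fit$center)
}

# Neck axis: the line through the head-circle center and the midshaft
# midpoint (midpoint of the medial- and lateral-shaft centroids).
neck_axis <- function(p, regions) {
  hd <- head_diameter(p, regions$head)
  m_med <- colMeans(p[regions$shaft_medial, , drop = FALSE])
  m_lat <- colMeans(p[regions$shaft_lateral, , drop = FALSE])
  mid <- (m_med + m_lat) / 2
  d <- hd$center - mid
  len <- sqrt(sum(d^2))
  if (len == 0) {
    abort("Head center coincides with midshaft midpoint.",
      class = "hipshape_error_degenerate"
    )
  }
  list(
    origin = mid, direction = d / len, head_center = hd$center,
    head_diameter = hd$diameter, head_rms = hd$fit_rms
  )
}

#' Femoral neck axis and width
#'
#' The neck axis is the line through the fitted head-circle center and the
#' midshaft midpoint. Width is the minimal distance between the superior and
#' inferior neck border segments measured along cross-lines perpendicular to
#' that axis: both borders are parameterized by their along-axis coordinate,
#' interpolated on a common grid, and the minimal perpendicular separation is
#' returned.
#'
#' @inheritParams head_diameter
#' @param superior_range,inferior_range Indices (>= 3 each, non-overlapping)
#'   of the superior and inferior neck border points.
#' @param regions Region configuration used for the head arc and shaft
#'   midpoint; see [femur_regions()].
#' @param n_grid Number of candidate perpendicular cuts.
#' @return List with `axis` (origin, direction, head center) and `neck_width`
#'   (mm).
#' @export
neck_axis_and_width <- function(points,
                                superior_range = femur_regions()$neck_superior,
                                inferior_range = femur_regions()$neck_inferior,
                                regions = femur_regions(),
                                n_grid = 200) {
  p <- as_point_matrix(points)
  if (length(superior_range) < 3 || length(inferior_range) < 3) {
    abort("Neck border ranges need at least 3 points each.",
      class = "hipshape_error_argument"
    )
  }
  if (length(intersect(superior_range, inferior_range)) > 0) {
    abort("Superior and inferior neck ranges overlap.",
      class = "hipshape_error_argument"
    )
  }
  ax <- neck_axis(p, regions)
  u <- ax$direction
  nv <- c(-u[2], u[1])
  coord <- function(idx) {
    q <- sweep(p[idx, , drop = FALSE], 2, ax$origin)
    list(t = q %*% u, d = q %*% nv)
  }
  sup <- coord(superior_range)
  inf <- coord(inferior_range)
  t_lo <- max(min(sup$t), min(inf$t))
  t_hi <- min(max(sup$t), max(inf$t))
  if (t_hi <= t_lo) {
    abort("Neck border segments do not overlap along the neck axis.",
      class = "hipshape_error_degenerate"
    )
  }
  grid <- seq(t_lo, t_hi, length.out = n_grid)
  d_sup <- approx(sup$t, sup$d, xout = grid, ties = mean)$y
  d_inf <- approx(inf$t, inf$d, xout = grid, ties = mean)$y
  width <- min(abs(d_sup - d_inf))
  list(axis = ax, neck_width = width)
}

#' Femoral neck length
#'
#' Distance along the neck axis from the head-circle center to the
#' intersection of the axis with the intertrochanteric line (the segment
#' joining the greater- and lesser-trochanter landmarks).
#'
#' @inheritParams neck_axis_and_width
#' @return Neck length in mm.
#' @export
neck_length <- function(points, regions = femur_regions()) {
  p <- as_point_matrix(points)
  ax <- neck_axis(p, regions)
  gt <- p[regions$greater_troch, ]
  lt <- p[regions$lesser_troch, ]
  seg <- lt - gt
  # Solve gt + q*seg = head_center + t*u  for (q, t).
  a <- cbind(seg, -ax$direction)
  if (abs(det(a)) < 1e-12) {
    abort("Neck axis is parallel to the intertrochanteric line.",
      class = "hipshape_error_degenerate"
    )
  }
  sol <- solve(a, ax$head_center - gt)
  intersection <- gt + sol[1] * seg
  sqrt(sum((ax$head_center - intersection)^2))
}

#' Geometric measures for a cohort of outlines
#'
#' Per-subject femoral head diameter, neck width and neck length (all mm),
#' computed on raw mm landmarks.
#'
#' @param landmarks Tidy landmark table in mm.
#' @param regions Region configuration; see [femur_regions()].
#' @return Tibble with `subject_id`, `head_diameter`, `head_fit_rms`,
#'   `neck_width`, `neck_length`. A warning (not an error) is raised for
#'   subjects with `neck_width >= head_diameter`, which is anatomically
#'   implausible.
#' @export
measure_geometry <- function(landmarks, regions = femur_regions()) {
  validate_landmarks(landmarks)
  m <- landmark_matrix(landmarks)
  out <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    p <- points_from_vec(m[i, ])
    hd <- head_diameter(p, regions$head)
    nw <- neck_axis_and_width(p,
      superior_range = regions$neck_superior,
      inferior_range = regions$neck_inferior, regions = regions
    )
    tibble::tibble(
      subject_id = rownames(m)[i],
      head_diameter = hd$diameter,
      head_fit_rms = hd$fit_rms,
      neck_width = nw$neck_width,
      neck_length = neck_length(p, regions)
    )
  })
  implausible <- out$neck_width >= out$head_diameter
  if (any(implausible)) {
    warn(paste0(
      "neck_width >= head_diameter (anatomically implausible) for: ",
      paste(out$subject_id[implausible], collapse = ", ")
    ))
  }
  out
}
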