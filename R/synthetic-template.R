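# Parametric 60-point right-proximal-femur outline template.
#
# The outline traces, in order: medial shaft -> lesser-trochanter bump ->
# inferior (medial) neck border -> femoral head arc -> superior neck border ->
# greater trochanter -> lateral shaft, i.e. from the lesser-trochanter side
# around the head to the opposite point on the femoral shaft. Coordinates are
# mm, x increasing medially, y increasing proximally (mathematical
# convention); a right hip traverses this path counter-clockwise.
#
# Point-index semantics (emitted as the template's `regions` metadata and
# consumed as `femur_regions()` defaults):
#   1:2   medial shaft          3:7   lesser-trochanter bump (tip = 5)
#   8:9   calcar transition     10:14 inferior neck border (straight)
#   15:36 head arc (on the head circle exactly)
#   37:41 superior neck border  42:43 saddle to greater trochanter
#   44    greater-trochanter peak     45:48 trochanter descent
#   49:60 lateral shaft
#
# The head arc lies exactly on a circle of the configured radius; the neck
# borders are straight lines parallel to the neck axis at half the configured
# neck width, so the geometric truth (head diameter, minimal neck width,
# axis/intertrochanteric-line intersection) is available in closed form.

quad_bezier <- function(p0, p1, p2, t) {
  cbind(
    (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
    (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  )
}

#' Template parameters for the synthetic femur outline
#'
#' Defaults are typical of an elderly female AP hip radiograph: head radius
#' 24 mm (diameter 48 mm), minimal neck width 31 mm, shaft width 30 mm.
#'
#' @param head_radius_mm Femoral head radius.
#' @param neck_width_mm Minimal femoral neck width.
#' @param shaft_width_mm Shaft width.
#' @param axis_angle_deg Angle of the neck/head axis from vertical.
#' @param axis_length_mm Distance from the midshaft anchor to the head
#'   center.
#' @param lt_bulge_mm Lesser-trochanter protrusion beyond the medial shaft
#'   line.
#' @param gt_peak_mm Greater-trochanter peak position `c(x, y)`.
#' @return Named list of template parameters.
#' @export
template_params <- function(head_radius_mm = 24,
                            neck_width_mm = 31,
                            shaft_width_mm = 30,
                            axis_angle_deg = 32,
                            axis_length_mm = 88,
                            lt_bulge_mm = 14,
                            gt_peak_mm = c(-17, 70)) {
  list(
    head_radius_mm = head_radius_mm,
    neck_width_mm = neck_width_mm,
    shaft_width_mm = shaft_width_mm,
    axis_angle_deg = axis_angle_deg,
    axis_length_mm = axis_length_mm,
    lt_bulge_mm = lt_bulge_mm,
    gt_peak_mm = gt_peak_mm
  )
}

#' Build the synthetic femur-outline template
#'
#' @param params Template parameters from [template_params()].
#' @return List of class `femur_template` with `points` (60 x 2, mm),
#'   `regions` (index semantics, see [femur_regions()]), `params`, and
#'   `truth` (closed-form head diameter, neck width, neck length).
#' @export
femur_template <- function(params = template_params()) {
  r <- params$head_radius_mm
  w <- params$neck_width_mm
  ws2 <- params$shaft_width_mm / 2
  if (r <= w / 2) {
    abort("Head radius must exceed half the neck width.",
      class = "hipshape_error_geometry"
    )
  }
  if (w <= 0 || ws2 <= 0 || params$axis_length_mm <= 0) {
    abort("Template widths and lengths must be positive.",
      class = "hipshape_error_geometry"
    )
  }

  # Shaft and trochanter scaffolding (independent of the axis).
  medial_shaft <- rbind(c(ws2, 6), c(ws2, 14))
  lt <- quad_bezier(
    c(ws2, 18), c(ws2 + params$lt_bulge_mm, 26), c(ws2 + 2, 34),
    seq(0, 1, length.out = 5)
  )
  lateral_shaft <- cbind(-ws2, seq(46, 2, length.out = 12))

  # Neck axis anchored the same way the measurement defines it: through the
  # head center and the midpoint of the medial/lateral shaft centroids
  # (lateral centroid over the shaft_lateral region, points 55:60).
  m_med <- colMeans(medial_shaft)
  m_lat <- colMeans(lateral_shaft[7:12, , drop = FALSE])
  m_axis <- (m_med + m_lat) / 2
  beta <- params$axis_angle_deg * pi / 180
  u <- c(sin(beta), cos(beta))
  nv <- c(cos(beta), -sin(beta)) # inferior-medial side of the axis
  cen <- m_axis + params$axis_length_mm * u

  a <- sqrt(r^2 - (w / 2)^2)
  j_inf <- cen - a * u + (w / 2) * nv
  j_sup <- cen - a * u - (w / 2) * nv
  n_inf0 <- j_inf - 22 * u
  n_sup0 <- j_sup - 26 * u

  lt_end <- lt[5, ]
  calcar <- quad_bezier(
    lt_end, c(0.6 * lt_end[1] + 0.4 * n_inf0[1], n_inf0[2] - 12), n_inf0,
    c(1 / 3, 2 / 3)
  )
  inf_neck <- outer(rep(1, 5), n_inf0) +
    outer(seq(0, 1, length.out = 5), j_inf - n_inf0)

  phi_i <- atan2(j_inf[2] - cen[2], j_inf[1] - cen[1])
  phi_s <- atan2(j_sup[2] - cen[2], j_sup[1] - cen[1])
  span <- (phi_s - phi_i) %% (2 * pi) # CCW from inferior to superior junction
  phis <- phi_i + span * seq_len(22) / 23
  head_arc <- cbind(cen[1] + r * cos(phis), cen[2] + r * sin(phis))

  sup_neck <- outer(rep(1, 5), j_sup) +
    outer(seq(0, 1, length.out = 5), n_sup0 - j_sup)

  gt_peak <- params$gt_peak_mm
  saddle <- quad_bezier(
    n_sup0, c((n_sup0[1] + gt_peak[1]) / 2, n_sup0[2] + 2), gt_peak,
    c(1 / 3, 2 / 3)
  )
  gt_descent <- quad_bezier(
    gt_peak, c(-ws2 - 6, 60), c(-ws2, 50),
    seq(0, 1, length.out = 5)
  )[-1, , drop = FALSE]

  points <- rbind(
    medial_shaft, # 1:2
    lt, # 3:7
    calcar, # 8:9
    inf_neck, # 10:14
    head_arc, # 15:36
    sup_neck, # 37:41
    saddle, # 42:43
    gt_peak, # 44
    gt_descent, # 45:48
    lateral_shaft # 49:60
  )
  dimnames(points) <- NULL
  stopifnot(nrow(points) == 60)

  regions <- femur_regions()

  # Closed-form geometric truth.
  gt_lm <- points[regions$greater_troch, ]
  lt_lm <- points[regions$lesser_troch, ]
  seg <- lt_lm - gt_lm
  amat <- cbind(seg, -u)
  if (abs(det(amat)) < 1e-12) {
    abort("Template axis parallel to intertrochanteric line.",
      class = "hipshape_error_geometry"
    )
  }
  sol <- solve(amat, cen - gt_lm)
  neck_len_true <- sqrt(sum((cen - (gt_lm + sol[1] * seg))^2))

  out <- list(
    points = points,
    regions = regions,
    params = params,
    axis = list(origin = m_axis, direction = u, head_center = cen),
    truth = list(
      head_diameter = 2 * r,
      neck_width = w,
      neck_length = neck_len_true
    )
  )
  class(out) <- "femur_template"
  if (!is_simple_outline(points)) {
    abort("Template parameters produce a self-intersecting outline.",
      class = "hipshape_error_geometry"
    )
  }
  if (outline_orientation(points) <= 0) {
    abort("Template parameters produce a left-side (clockwise) outline.",
      class = "hipshape_error_geometry"
    )
  }
  out
}

#' @export
print.femur_template <- function(x, ...) {
  cat(
    "Synthetic femur-outline template (60 points)\n",
    "  head diameter: ", x$truth$head_diameter, " mm\n",
    "  neck width:    ", x$truth$neck_width, " mm\n",
    "  neck length:   ", round_half_up(x$truth$neck_length, 1), " mm\n",
    sep = ""
  )
  invisible(x)
}

#' Check that an outline polyline is simple (non-self-intersecting)
#'
#' Pairwise segment-intersection sweep over the open polyline.
#'
#' @param points `k x 2` point matrix.
#' @return `TRUE` if no two non-adjacent segments intersect.
#' @export
is_simple_outline <- function(points) {
  p <- as_point_matrix(points)
  n <- nrow(p) - 1
  seg_a <- p[seq_len(n), , drop = FALSE]
  seg_b <- p[seq_len(n) + 1, , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    d1 <- cross2(
      seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2],
      seg_a[js, 1], seg_a[js, 2]
    )
    d2 <- cross2(
      seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2],
      seg_b[js, 1], seg_b[js, 2]
    )
    d3 <- cross2(
      seg_a[js, 1], seg_a[js, 2], seg_b[js, 1], seg_b[js, 2],
      rep(seg_a[i, 1], length(js)), rep(seg_a[i, 2], length(js))
    )
    d4 <- cross2(
      seg_a[js, 1], seg_a[js, 2], seg_b[js, 1], seg_b[js, 2],
      rep(seg_b[i, 1], length(js)), rep(seg_b[i, 2], length(js))
    )
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Signed orientation of a closed outline
#'
#' Shoelace signed area of the polygon obtained by closing the outline.
#' Right-proximal-femur outlines in this package's convention traverse
#' counter-clockwise (positive area); a mirrored (left-side) outline is
#' negative.
#'
#' @param points `k x 2` point matrix.
#' @return Signed area (mm^2 for mm input).
#' @export
outline_orientation <- function(points) {
  p <- as_point_matrix(points)
  x <- p[, 1]
  y <- p[, 2]
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Assert that an outline is a right-side femur
#'
#' @param points `k x 2` point matrix (ordered per the outline contract).
#' @return `TRUE` invisibly; errors for a clockwise (mirrored/left) outline.
#' @export
check_right_side <- function(points) {
  if (outline_orientation(points) <= 0) {
    abort("Outline is clockwise: looks like a mirrored/left-side femur.",
      class = "hipshape_error_left_side"
    )
  }
  invisible(TRUE)
}
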