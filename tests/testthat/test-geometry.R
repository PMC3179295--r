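circle_points <- function(r, n = 8, arc = 2 * pi, center = c(0, 0), start = 0) {
  th <- start + arc * (seq_len(n) - 1) / max(1, n - 1)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

test_that("circle fit recovers exact circles and tolerates landmark noise", {
  p <- circle_points(24, n = 8)
  hd <- head_diameter(p, head_range = 1:8)
  expect_equal(hd$diameter, 48, tolerance = 1e-9)
  expect_lt(hd$fit_rms, 1e-9)

  # Monte-Carlo: N(0, 0.2 mm) noise keeps the diameter within 0.5 mm.
  errs <- vapply(1:100, function(seed) {
    noisy <- p + withr::with_seed(seed, matrix(rnorm(16, sd = 0.2), 8, 2))
    abs(head_diameter(noisy, 1:8)$diameter - 48)
  }, numeric(1))
  expect_lt(max(errs), 0.5)
})

test_that("arc extent does not bias the fitted diameter", {
  for (arc_deg in c(90, 120, 180, 270)) {
    p <- circle_points(17.5, n = 12, arc = arc_deg * pi / 180, start = 0.4)
    expect_equal(head_diameter(p, 1:12)$diameter, 35, tolerance = 1e-9)
  }
})

test_that("collinear points make the circle fit fail loudly", {
  p <- cbind(1:8, 2 * (1:8) + 3)
  expect_error(head_diameter(p, 1:8), class = "hipshape_error_degenerate")
})

test_that("template measures match the generator's closed-form truth", {
  p <- fix_template$points
  truth <- fix_template$truth
  expect_equal(head_diameter(p)$diameter, truth$head_diameter, tolerance = 1e-9)
  nw <- neck_axis_and_width(p)
  expect_lt(abs(nw$neck_width - truth$neck_width) / truth$neck_width, 0.02)
  nl <- neck_length(p)
  expect_lt(abs(nl - truth$neck_length) / truth$neck_length, 0.02)
})

test_that("measures are rigid-invariant and homogeneous of degree 1", {
  p <- fix_template$points
  base <- measure_geometry(landmark_tibble(matrix(t(p), nrow = 1), "t"))
  moved <- transform_points(p, theta = 0.6, scale = 1, shift = c(40, -25))
  m2 <- measure_geometry(landmark_tibble(matrix(t(moved), nrow = 1), "t"))
  for (v in c("head_diameter", "neck_width", "neck_length")) {
    expect_lt(abs(m2[[v]] - base[[v]]) / base[[v]], 1e-9)
  }
  scaled <- measure_geometry(landmark_tibble(matrix(t(1.1 * p), nrow = 1), "t"))
  for (v in c("head_diameter", "neck_width", "neck_length")) {
    expect_equal(scaled[[v]], 1.1 * base[[v]], tolerance = 1e-9)
  }
})

test_that("neck width is the minimal cross-section, matching a brute-force cut search", {
  # Trumpet deformation: flare the distal end of the inferior border outward.
  p <- fix_template$points
  regions <- femur_regions()
  ax <- neck_axis_and_width(p)$axis
  u <- ax$direction
  nv <- c(-u[2], u[1])
  inf_idx <- regions$neck_inferior
  t_inf <- as.vector(sweep(p[inf_idx, ], 2, ax$origin) %*% u)
  flare <- 4 * (max(t_inf) - t_inf) / diff(range(t_inf)) # 0 at head end
  side <- sign(sum(nv * (p[inf_idx[1], ] - ax$origin))) # outward direction
  p2 <- p
  p2[inf_idx, ] <- p[inf_idx, ] + side * outer(flare, nv)

  res <- neck_axis_and_width(p2)

  # Oracle: dense perpendicular cuts intersected with the border polylines.
  cut_width <- function(points, sup_idx, inf_idx, axis, tt) {
    cross_at <- function(idx) {
      q <- sweep(points[idx, , drop = FALSE], 2, axis$origin)
      tq <- q %*% axis$direction
      dq <- q %*% c(-axis$direction[2], axis$direction[1])
      for (i in seq_len(length(idx) - 1)) {
        if ((tq[i] - tt) * (tq[i + 1] - tt) <= 0 && tq[i] != tq[i + 1]) {
          w <- (tt - tq[i]) / (tq[i + 1] - tq[i])
          return(dq[i] + w * (dq[i + 1] - dq[i]))
        }
      }
      NA_real_
    }
    abs(cross_at(sup_idx) - cross_at(inf_idx))
  }
  tt_grid <- seq(min(t_inf), max(t_inf), length.out = 2000)
  widths <- vapply(tt_grid, function(tt) {
    cut_width(p2, regions$neck_superior, inf_idx, res$axis, tt)
  }, numeric(1))
  expect_equal(res$neck_width, min(widths, na.rm = TRUE), tolerance = 1e-6)
  # The flare widened the far end, so the minimum is what is reported.
  expect_lt(res$neck_width, max(widths, na.rm = TRUE) - 1)
})

test_that("overlapping or undersized neck ranges are rejected", {
  p <- fix_template$points
  expect_error(
    neck_axis_and_width(p, superior_range = 37:41, inferior_range = 39:43),
    class = "hipshape_error_argument"
  )
  expect_error(
    neck_axis_and_width(p, superior_range = 37:38, inferior_range = 10:14),
    class = "hipshape_error_argument"
  )
})

test_that("the mode-4 analog trades neck length against head size", {
  cfg <- fix_config
  truth <- fix_cohort$truth
  d4 <- truth$basis[, 4]
  lam4 <- truth$lambda[4]
  base_vec <- vec_from_points(fix_template$points)
  shape_at <- function(s) points_from_vec(base_vec + s * sqrt(lam4) * d4)
  geo <- function(p) {
    tibble::tibble(
      nl = neck_length(p),
      hd = head_diameter(p)$diameter,
      nw = neck_axis_and_width(p)$neck_width
    )
  }
  lo <- geo(shape_at(-2))
  mid <- geo(shape_at(0))
  hi <- geo(shape_at(2))
  expect_gt(hi$nl, lo$nl) # longer neck at +SD
  expect_lt(hi$hd, lo$hd) # smaller head at +SD
  expect_lt(hi$nw, lo$nw) # narrower neck at +SD
  expect_gt(hi$nl, mid$nl)
  expect_lt(lo$nl, mid$nl)
})

test_that("implausible width/diameter relations warn but do not error", {
  p <- fix_template$points
  regions <- femur_regions(head = 15:36)
  # Shrink the head circle drastically so width exceeds the diameter.
  cen <- head_diameter(p)$center
  p2 <- p
  p2[15:36, ] <- 0.3 * sweep(p[15:36, ], 2, cen) + matrix(cen, 22, 2, byrow = TRUE)
  expect_warning(
    measure_geometry(landmark_tibble(matrix(t(p2), nrow = 1), "t"), regions),
    "implausible"
  )
})
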