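test_that("planted noiseless low-rank cohorts have exactly that rank", {
  withr::local_seed(42)
  k <- 12
  q <- qr.Q(qr(matrix(rnorm(2 * k * 3), 2 * k, 3)))
  s <- matrix(rnorm(60 * 3), 60, 3)
  x <- s %*% (c(4, 2, 1) * t(q)) # planted eigenvalue scales
  m <- shape_pca(x, n_modes = 3)
  expect_equal(length(m$eigenvalues), 3)
  # Requesting more modes than the rank fails, naming the achievable rank.
  err <- expect_error(shape_pca(x, n_modes = 5), class = "hipshape_error_rank")
  expect_match(conditionMessage(err), "3")
})

test_that("eigen-decomposition agrees with a dense covariance oracle", {
  withr::local_seed(7)
  x <- matrix(rnorm(20 * 16), 20, 16)
  m <- shape_pca(x, n_modes = 10)
  # Oracle: explicit covariance matrix + dense symmetric eigensolver.
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  expect_equal(m$eigenvalues, ev$values[seq_along(m$eigenvalues)],
    tolerance = 1e-8
  )
  # Span agreement via principal angles of the leading 10-dim subspaces.
  sv <- svd(t(m$modes) %*% ev$vectors[, 1:10])$d
  angles <- acos(pmin(1, sv))
  expect_lt(max(angles), 1e-6)
})

test_that("total variance is conserved in the spectrum", {
  x <- fix_alignment$shapes
  m <- fix_model
  expect_equal(
    sum(m$eigenvalues), sum(diag(stats::cov(x))),
    tolerance = 1e-9 * sum(m$eigenvalues)
  )
  expect_true(all(diff(m$eigenvalues) <= 0))
  expect_lte(sum(m$variance_fractions), 1 + 1e-12)
  # Orthonormal modes.
  expect_equal(t(m$modes) %*% m$modes, diag(10), tolerance = 1e-10)
})

test_that("training scores are standardized: mean 0, SD 1 per mode", {
  s <- as.matrix(fix_scores[, -1])
  expect_lt(max(abs(colMeans(s))), 1e-8)
  expect_equal(unname(apply(s, 2, sd)), rep(1, 10), tolerance = 1e-6)
})

test_that("scoring matches construction: mean maps to zero, planted offsets recover", {
  m <- fix_model
  x_mean <- matrix(m$mean_shape, 1)
  expect_equal(max(abs(as.matrix(score_shapes(m, x_mean)[, -1]))), 0,
    tolerance = 1e-10
  )
  x4 <- matrix(m$mean_shape + 2 * sqrt(m$eigenvalues[4]) * m$modes[, 4], 1)
  s4 <- as.matrix(score_shapes(m, x4)[, -1])
  expect_equal(s4[1, "mode4"], c(mode4 = 2), tolerance = 1e-8)
  expect_lt(max(abs(s4[1, -4])), 1e-8)
})

test_that("score/reconstruct round-trips at full rank", {
  withr::local_seed(11)
  x <- matrix(rnorm(30 * 10), 30, 10)
  m <- shape_pca(x, n_modes = 10) # full column rank here
  sc <- as.matrix(score_shapes(m, x)[, -1])
  for (i in c(1, 17, 30)) {
    rec <- reconstruct_shape(m, sc[i, ])
    expect_lt(sqrt(mean((vec_from_points(rec) - x[i, ])^2)), 1e-8)
  }
  # All-zero scores give the mean shape exactly.
  expect_equal(vec_from_points(reconstruct_shape(m, rep(0, 10))), unname(m$mean_shape))
})

test_that("mode gallery is linear and symmetric about the mean", {
  g0 <- mode_gallery(fix_model, 4, sd_values = 0)
  expect_equal(cbind(g0$x, g0$y) |> t() |> as.vector(), unname(fix_model$mean_shape))
  g <- mode_gallery(fix_model, 4, sd_values = c(-2, 2))
  neg <- g[g$sd == -2, ]
  pos <- g[g$sd == 2, ]
  expect_equal(neg$x + pos$x, 2 * g0$x, tolerance = 1e-10)
  expect_equal(neg$y + pos$y, 2 * g0$y, tolerance = 1e-10)
  expect_error(mode_gallery(fix_model, 11), class = "hipshape_error_argument")
})

test_that("variance-target retention picks the smallest sufficient mode count", {
  m95 <- shape_pca(fix_alignment, variance_target = 0.95)
  cf <- cumsum(m95$variance_fractions)
  expect_gte(cf[m95$n_modes], 0.95)
  if (m95$n_modes > 1) expect_lt(cf[m95$n_modes - 1], 0.95)
  expect_lte(m95$n_modes, 10)
})

test_that("planted spectrum and subspace are recovered on the synthetic cohort", {
  # Eigenvalue recovery: a single n = 399 draw has ~sqrt(2/n) = 7% sampling
  # noise per eigenvalue, so the 15% bound is checked on the mean relative
  # error across three independent cohorts.
  rel <- rowMeans(vapply(1:3, function(seed) {
    co <- if (seed == 1) fix_cohort else simulate_cohort(fix_config, seed = seed)
    al <- if (seed == 1) fix_alignment else gpa_align(co$landmarks)
    mm <- if (seed == 1) fix_model else shape_pca(al, n_modes = 10)
    size <- mean(al$centroid_sizes)
    abs(mm$eigenvalues[1:10] * size^2 - co$truth$lambda) / co$truth$lambda
  }, numeric(10)))
  expect_lt(max(rel[1:5]), 0.15) # well-separated leading eigenvalues

  m <- fix_model
  truth <- fix_cohort$truth

  # Subspace recovery: principal angles between planted basis (similarity
  # components removed, per construction) and estimated modes, after undoing
  # the global rotation of the aligned frame.
  mean_pts <- points_from_vec(m$mean_shape)
  templ_pts <- truth$template$points
  templ_unit <- sweep(templ_pts, 2, colMeans(templ_pts)) / centroid_size(templ_pts)
  r <- optimal_rotation(templ_unit, mean_pts)
  th <- atan2(r[2, 1], r[1, 1])
  planted_rot <- apply(truth$basis, 2, function(v) {
    vec_from_points(points_from_vec(v) %*% t(rotation_matrix(th)))
  })
  sv <- svd(t(m$modes) %*% planted_rot)$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_lt(max(angles), 10)
})

test_that("held-out shapes generated from the model score with SD near 1", {
  withr::local_seed(23)
  m <- fix_model
  n_new <- 300
  z <- matrix(rnorm(n_new * 10), n_new, 10)
  x_new <- matrix(m$mean_shape, n_new, 2 * m$k, byrow = TRUE) +
    z %*% (sqrt(m$eigenvalues[1:10]) * t(m$modes))
  s_new <- as.matrix(score_shapes(m, x_new)[, -1])
  sds <- apply(s_new, 2, sd)
  expect_lt(max(abs(sds - 1)), 3 / sqrt(2 * n_new))
})

test_that("scoring a shape outside the model span errors on zero modes", {
  withr::local_seed(5)
  x <- matrix(rnorm(8 * 6), 8, 6)
  m <- shape_pca(x, n_modes = 5)
  m$eigenvalues[5] <- 0 # simulate a zero-variance retained mode
  probe <- matrix(m$mean_shape + m$modes[, 5], 1)
  expect_error(score_shapes(m, probe), class = "hipshape_error_out_of_span")
})
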