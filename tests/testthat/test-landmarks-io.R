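test_that("pixel pitch converts dpi to mm at printed precision", {
  expect_equal(pixel_pitch_mm(150), 0.169)
  expect_equal(pixel_pitch_mm(25.4), 1.000)
  expect_equal(pixel_pitch_mm(300), 0.085) # 25.4/300 = 0.084666..., half-up
  expect_error(pixel_pitch_mm(0), class = "hipshape_error_argument")
  expect_error(pixel_pitch_mm(-150), class = "hipshape_error_argument")
})

test_that("CSV landmarks round-trip and pixel scaling applies", {
  lm_px <- landmark_tibble(
    matrix(round(runif(2 * 120, 10, 900)), nrow = 2),
    subject_id = c("a", "b")
  )
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm_px, f, "csv")

  back <- read_landmarks(f, "csv")
  expect_equal(back$x, lm_px$x)
  expect_equal(back$y, lm_px$y)
  expect_equal(unique(back$subject_id), c("a", "b"))

  mm <- read_landmarks(f, "csv", pixel_spacing_mm = 0.169)
  expect_equal(mm$x, lm_px$x * 0.169)
  expect_equal(mm$y, lm_px$y * 0.169)
})

test_that("TPS dialect reads the same subjects as the equivalent CSV", {
  lm <- landmark_tibble(matrix(rnorm(3 * 120), nrow = 3),
    subject_id = c("s1", "s2", "s3")
  )
  fc <- withr::local_tempfile(fileext = ".csv")
  ft <- withr::local_tempfile(fileext = ".tps")
  write_landmarks(lm, fc, "csv")
  write_landmarks(lm, ft, "tps")
  from_csv <- read_landmarks(fc, "csv")
  from_tps <- read_landmarks(ft, "tps")
  expect_equal(from_tps$subject_id, from_csv$subject_id)
  expect_equal(from_tps$x, from_csv$x, tolerance = 1e-6)
  expect_equal(from_tps$y, from_csv$y, tolerance = 1e-6)
})

test_that("a TPS SCALE line converts to mm like explicit pixel spacing", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c(
    "LM=3", "10 20", "30 40", "50 60", "ID=sub1", "SCALE=0.169"
  ), f)
  lm <- read_landmarks(f, "tps")
  expect_equal(lm$x, c(10, 30, 50) * 0.169)
})

test_that("mixed point counts raise a structured error naming the subject", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c(
    "LM=4", "0 0", "1 0", "1 1", "0 1", "ID=good1",
    "LM=4", "0 0", "2 0", "2 2", "0 2", "ID=good2",
    "LM=3", "0 0", "1 0", "1 1", "ID=short"
  ), f)
  err <- expect_error(read_landmarks(f, "tps"), class = "hipshape_error_mixed_k")
  expect_match(conditionMessage(err), "short")

  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,x1,y1,x2,y2",
    "a,0,0,1,1",
    "b,0,0,1,"
  ), fc)
  err2 <- expect_error(read_landmarks(fc, "csv"), class = "hipshape_error_mixed_k")
  expect_match(conditionMessage(err2), "b")
})

test_that("unparseable TPS records report the line number", {
  f <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=2", "0 0", "oops not_a_number", "ID=x"), f)
  err <- expect_error(read_landmarks(f, "tps"), class = "hipshape_error_io")
  expect_match(conditionMessage(err), "line")
})

test_that("flip_y negates the vertical axis for image-origin files", {
  lm <- landmark_tibble(matrix(1:8, nrow = 1), subject_id = "a")
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, f, "csv")
  flipped <- read_landmarks(f, "csv", flip_y = TRUE)
  expect_equal(flipped$y, -lm$y)
  expect_equal(flipped$x, lm$x)
})

test_that("acceptability filter reproduces exclusion arithmetic", {
  k <- 8
  n <- 176
  lm <- landmark_tibble(matrix(rnorm(n * 2 * k), nrow = n))
  ids <- unique(lm$subject_id)
  flags <- setNames(rep(TRUE, n), ids)
  flags[sample(ids, 8)] <- FALSE
  res <- filter_acceptable(lm, flags)
  expect_equal(res$report$n_kept, 168)
  expect_equal(res$report$pct_excluded, 4.5)
  expect_equal(length(unique(res$kept$subject_id)), 168)

  all_ok <- filter_acceptable(lm, setNames(rep(TRUE, n), ids))
  expect_equal(all_ok$report$pct_excluded, 0.0)
  expect_equal(nrow(all_ok$kept), nrow(lm))

  lm7 <- landmark_tibble(matrix(rnorm(7 * 2 * k), nrow = 7))
  ids7 <- unique(lm7$subject_id)
  res7 <- filter_acceptable(lm7, setNames(c(rep(FALSE, 3), rep(TRUE, 4)), ids7))
  expect_equal(res7$report$n_kept, 4)
  expect_equal(res7$report$pct_excluded, 42.9)

  expect_error(filter_acceptable(lm[0, ], logical(0)),
    class = "hipshape_error_empty_cohort"
  )
})

test_that("kept plus excluded always equals the cohort size", {
  k <- 5
  for (seed in 1:10) {
    n <- withr::with_seed(seed, sample(3:40, 1))
    lm <- landmark_tibble(matrix(rnorm(n * 2 * k), nrow = n))
    flags <- withr::with_seed(seed, runif(n) < 0.7)
    names(flags) <- unique(lm$subject_id)
    rep <- filter_acceptable(lm, flags)$report
    expect_equal(rep$n_kept + rep$n_excluded, rep$n_total)
  }
})

test_that("subject-table validation enforces the record invariants", {
  good <- tibble::tibble(
    subject_id = c("a", "b"), age = c(70, 72), bmd_fn = c(0.6, 0.7),
    fracture = c(TRUE, FALSE),
    fracture_site = c("femoral_neck", "none")
  )
  expect_s3_class(validate_subjects(good), "tbl_df")

  bad_site <- good
  bad_site$fracture_site <- c("none", "femoral_neck") # control with a site
  err <- expect_error(validate_subjects(bad_site), class = "hipshape_error_subjects")
  expect_match(conditionMessage(err), "b")

  bad_bmd <- good
  bad_bmd$bmd_fn[1] <- -0.1
  expect_error(validate_subjects(bad_bmd), class = "hipshape_error_subjects")

  f <- withr::local_tempfile(fileext = ".csv")
  write_subjects(good, f)
  expect_equal(read_subjects(f)$age, good$age)
})
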