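# Shared fixtures, built once per test run. All fixtures are generated in
# code under fixed seeds; no stored data.

fix_config <- cohort_config() # the default study conditions (n = 399)
fix_cohort <- simulate_cohort(fix_config, seed = 1)
fix_alignment <- gpa_align(fix_cohort$landmarks)
fix_model <- shape_pca(fix_alignment, n_modes = 10)
fix_scores <- score_shapes(fix_model, fix_alignment)
fix_data <- dplyr::left_join(fix_scores, fix_cohort$subjects, by = "subject_id")
fix_template <- femur_template()

# Apply one similarity transform (rotation theta, scale s, translation t) to
# a k x 2 point matrix.
transform_points <- function(p, theta = 0, scale = 1, shift = c(0, 0)) {
  r <- rotation_matrix(theta)
  sweep(scale * p %*% t(r), 2, -shift)
}

# A small irregular but non-degenerate test shape.
blob_shape <- function(k = 10, seed = 99) {
  withr::with_seed(seed, matrix(rnorm(2 * k, sd = 5), k, 2))
}

# Direct simulation of mode-score/covariate data with a logistic outcome,
# for risk-model unit tests that do not need landmarks.
sim_risk_data <- function(n = 400, beta = rep(0, 10), prevalence = 0.42,
                          seed = 1) {
  withr::with_seed(seed, {
    s <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("mode", 1:10)))
    age <- rnorm(n, 71, 4.5)
    bmi <- rnorm(n, 26, 4.2)
    eta <- as.vector(s %*% beta)
    alpha <- stats::uniroot(
      function(a) mean(plogis(a + eta)) - prevalence, c(-20, 20)
    )$root
    y <- runif(n) < plogis(alpha + eta)
    dplyr::bind_cols(
      tibble::as_tibble(s),
      tibble::tibble(age = age, bmi = bmi, fracture = y)
    )
  })
}
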