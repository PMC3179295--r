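# Random-relabeling quality control: reassign case/control status at a
# specified case-to-control ratio and verify that no shape mode associates
# with the shuffled outcome.

#' Relabeling plan at a case-to-control ratio
#'
#' With `ratio` controls per case, the case count is `floor(n / (1 + ratio))`
#' (which reproduces a 167/232 split at n = 399, ratio 1.38).
#'
#' @param n Number of subjects.
#' @param ratio Controls per case (positive).
#' @return Tibble with `n`, `ratio`, `n_cases`, `n_controls`.
#' @export
#' @examples
#' relabel_plan(399, 1.38)
relabel_plan <- function(n, ratio) {
  if (n < 2) abort("Need n >= 2.", class = "hipshape_error_argument")
  check_positive_scalar(ratio, "ratio")
  n_cases <- floor(n / (1 + ratio))
  if (n_cases < 1) {
    abort("Ratio leaves zero cases.", class = "hipshape_error_argument")
  }
  tibble::tibble(
    n = as.integer(n), ratio = ratio,
    n_cases = as.integer(n_cases), n_controls = as.integer(n - n_cases)
  )
}

#' Randomly reassign case/control labels
#'
#' Draws exactly `floor(n / (1 + ratio))` case positions uniformly without
#' replacement. With `seed` supplied the draw is reproducible and the
#' caller's RNG state is untouched.
#'
#' @inheritParams relabel_plan
#' @param seed Optional integer seed.
#' @return Logical vector of length `n`; `TRUE` = relabeled case.
#' @export
random_relabel <- function(n, ratio, seed = NULL) {
  plan <- relabel_plan(n, ratio)
  draw <- function() {
    labels <- rep(FALSE, n)
    labels[sample.int(n, plan$n_cases)] <- TRUE
    labels
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Null-association check by random relabeling
#'
#' For each replicate and each case-to-control ratio, case/control status is
#' reassigned at random and the adjusted 10-mode logistic model is refit
#' against the shuffled outcome; per-mode Wald p-values are recorded. Because
#' the labels carry no information, each mode should be "significant" at
#' level `alpha` in about `alpha` of replicates; the summary flags modes
#' whose significant fraction falls outside the binomial 99% band around
#' `alpha`. Replicates whose fit does not converge are counted and excluded
#' from the fractions.
#'
#' @param data Data frame with the mode-score columns and adjustment
#'   covariates (outcome column is ignored — labels are redrawn).
#' @param modes Mode-score column names (default `mode1..mode10`).
#' @param adjust Adjustment covariates (default age, BMI, femoral-neck BMD,
#'   matching the mode-association model).
#' @param ratios Case-to-control ratios to test.
#' @param n_reps Replicates per ratio.
#' @param alpha Significance level tested (default 0.05).
#' @param seed Master seed; replicate r at ratio index i uses a sub-seed
#'   derived deterministically from it.
#' @return Tibble with one row per ratio x mode: `ratio`, `mode`, `n_reps`,
#'   `n_converged`, `n_significant`, `frac_significant`, binomial 99% bounds,
#'   and `within_null_bounds`. The overall conclusion (`TRUE` when every
#'   mode/ratio cell is inside its bounds) is in attribute
#'   `consistent_with_null`.
#' @export
null_association_check <- function(data, modes = paste0("mode", 1:10),
                                   adjust = c("age", "bmi", "bmd_fn"),
                                   ratios = c(1, 1.38, 2),
                                   n_reps = 200, alpha = 0.05, seed = 1) {
  adjust <- intersect(adjust, names(data))
  n <- nrow(data)
  out <- purrr::map_dfr(seq_along(ratios), function(ri) {
    ratio <- ratios[ri]
    pmat <- matrix(NA_real_, nrow = n_reps, ncol = length(modes))
    converged <- logical(n_reps)
    for (r in seq_len(n_reps)) {
      sub_seed <- (seed + 7919L * ri + 104729L * r) %% .Machine$integer.max
      labels <- random_relabel(n, ratio, seed = sub_seed)
      dat <- data
      dat$.relabel <- labels
      fit <- tryCatch(
        fit_fracture_model(dat, modes, adjust = adjust, outcome = ".relabel"),
        error = function(e) NULL
      )
      if (!is.null(fit) && fit$converged) {
        converged[r] <- TRUE
        td <- tidy(fit)
        pmat[r, ] <- td$p.value[match(modes, td$term)]
      }
    }
    n_conv <- sum(converged)
    lo <- qbinom(0.005, n_conv, alpha)
    hi <- qbinom(0.995, n_conv, alpha)
    tibble::tibble(
      ratio = ratio,
      mode = modes,
      n_reps = n_reps,
      n_converged = n_conv,
      n_significant = colSums(pmat[converged, , drop = FALSE] < alpha),
      frac_significant = n_significant / n_conv,
      bound_low = lo / n_conv,
      bound_high = hi / n_conv,
      within_null_bounds = n_significant >= lo & n_significant <= hi
    )
  })
  attr(out, "consistent_with_null") <- all(out$within_null_bounds)
  out
}
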