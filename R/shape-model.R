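# PCA point-distribution model on Procrustes-aligned outlines: modes of
# variation, eigenvalue spectrum, SD-unit mode scores, reconstruction, and
# +/- SD mode galleries.

#' Fit a PCA point-distribution model
#'
#' Principal components ("modes of variation") of the aligned coordinate
#' vectors about their sample mean, with the sample covariance divisor
#' `n - 1`. Modes are sorted by decreasing eigenvalue; each eigenvector's sign
#' is fixed by making its largest-magnitude entry positive, so fits are
#' reproducible across platforms. By default 10 modes are retained; supplying
#' `variance_target` instead retains the smallest number of modes whose
#' variance fractions sum to at least the target.
#'
#' @param alignment A [gpa_align()] result (or an n x 2k matrix of aligned
#'   coordinates).
#' @param n_modes Number of modes to retain (default 10). Ignored when
#'   `variance_target` is given.
#' @param variance_target Optional fraction in (0, 1]; retain the smallest
#'   number of modes reaching this cumulative variance fraction.
#' @return An object of class `shape_model`: `mean_shape` (2k), `modes`
#'   (2k x m orthonormal), `eigenvalues` (all positive eigenvalues),
#'   `variance_fractions`, `n_modes`, `k`, `n`.
#' @export
shape_pca <- function(alignment, n_modes = 10, variance_target = NULL) {
  x <- if (inherits(alignment, "gpa_alignment")) alignment$shapes else as.matrix(alignment)
  n <- nrow(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  lambda <- pc$sdev^2
  rank <- sum(lambda > max(lambda) * 1e-12)
  lambda <- lambda[seq_len(rank)]
  fractions <- lambda / sum(lambda)
  if (!is.null(variance_target)) {
    if (variance_target <= 0 || variance_target > 1) {
      abort("`variance_target` must lie in (0, 1].",
        class = "hipshape_error_argument"
      )
    }
    n_modes <- which(cumsum(fractions) >= variance_target - 1e-12)[1]
  }
  if (n_modes > rank) {
    abort(
      paste0(
        "Requested ", n_modes, " modes but the aligned cohort has rank ",
        rank, "."
      ),
      class = "hipshape_error_rank"
    )
  }
  if (n < n_modes + 1) {
    abort("Need at least n_modes + 1 shapes.", class = "hipshape_error_argument")
  }
  modes <- pc$rotation[, seq_len(n_modes), drop = FALSE]
  # Deterministic sign: largest-|entry| of each mode made positive.
  flip <- vapply(seq_len(n_modes), function(j) {
    v <- modes[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  modes <- sweep(modes, 2, flip, `*`)
  structure(
    list(
      mean_shape = pc$center,
      modes = unname(modes),
      eigenvalues = lambda,
      variance_fractions = fractions,
      n_modes = n_modes,
      k = ncol(x) / 2,
      n = n
    ),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat(
    "Point-distribution model\n",
    "  landmarks: ", x$k, "  subjects: ", x$n, "\n",
    "  retained modes: ", x$n_modes, " of rank ", length(x$eigenvalues), "\n",
    "  variance captured: ",
    round_half_up(100 * sum(x$variance_fractions[seq_len(x$n_modes)]), 1),
    "%\n",
    sep = ""
  )
  invisible(x)
}

#' Eigenvalue table of a shape model
#'
#' @param x A `shape_model`.
#' @param ... Unused.
#' @return Tibble with `mode`, `eigenvalue`, `variance_fraction`,
#'   `cumulative_fraction`, and `retained`.
#' @export
tidy.shape_model <- function(x, ...) {
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    variance_fraction = x$variance_fractions,
    cumulative_fraction = cumsum(x$variance_fractions),
    retained = seq_along(x$eigenvalues) <= x$n_modes
  )
}

#' @export
glance.shape_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, k = x$k, n_modes = x$n_modes,
    variance_captured = sum(x$variance_fractions[seq_len(x$n_modes)]),
    total_variance = sum(x$eigenvalues)
  )
}

#' Score subjects on the model's modes, in SD units
#'
#' Raw coefficients are `b = t(Phi) (x - mean)`; SD-unit scores divide each
#' coefficient by the square root of the mode's eigenvalue, so over the
#' training cohort every mode-score column has mean 0 and SD 1. Each hip is
#' thereby expressed as standard deviations from the mean along each mode.
#'
#' @param model A [shape_pca()] fit.
#' @param alignment A `gpa_alignment` (or aligned coordinate matrix) with the
#'   same k as the model.
#' @return Tibble with `subject_id` and one `mode<j>` column per retained
#'   mode (SD units).
#' @export
score_shapes <- function(model, alignment) {
  x <- if (inherits(alignment, "gpa_alignment")) alignment$shapes else as.matrix(alignment)
  ids <- if (inherits(alignment, "gpa_alignment")) {
    alignment$subject_ids
  } else {
    rownames(x) %||% paste0("s", seq_len(nrow(x)))
  }
  if (ncol(x) != 2 * model$k) {
    abort("Model and cohort landmark counts differ.",
      class = "hipshape_error_argument"
    )
  }
  centered <- sweep(x, 2, model$mean_shape)
  b <- centered %*% model$modes
  lam <- model$eigenvalues[seq_len(model$n_modes)]
  zero <- lam <= 0
  if (any(zero) && any(abs(b[, zero]) > 1e-8)) {
    abort("Nonzero coefficient on a zero-variance mode (out-of-span shape).",
      class = "hipshape_error_out_of_span"
    )
  }
  s <- sweep(b, 2, sqrt(lam), `/`)
  colnames(s) <- paste0("mode", seq_len(model$n_modes))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(s))
}

#' Reconstruct a shape from SD-unit mode scores
#'
#' Computes `mean + sum_j s_j sqrt(lambda_j) phi_j`. With full-rank scores of
#' a training subject this reproduces that subject's aligned shape.
#'
#' @param model A [shape_pca()] fit.
#' @param scores Numeric vector of SD-unit scores (length at most the number
#'   of retained modes; shorter vectors imply 0 for the remaining modes).
#' @return A `k x 2` point matrix.
#' @export
reconstruct_shape <- function(model, scores) {
  m <- model$n_modes
  if (length(scores) > m) {
    abort("More scores than retained modes.", class = "hipshape_error_argument")
  }
  s <- rep(0, m)
  s[seq_along(scores)] <- scores
  v <- model$mean_shape +
    as.vector(model$modes %*% (s * sqrt(model$eigenvalues[seq_len(m)])))
  points_from_vec(v)
}

#' Mode gallery: reconstructions along an SD grid
#'
#' Reconstructs the outline at each requested number of SDs along a single
#' mode (all other modes at 0), the standard way of visualizing what a mode
#' of variation does (e.g. the mean flanked by -2 SD and +2 SD).
#'
#' @param model A [shape_pca()] fit.
#' @param mode Mode index (1-based, within the retained modes).
#' @param sd_values Numeric grid of SD values (default `c(-2, 0, 2)`).
#' @return Tibble with `mode`, `sd`, `point`, `x`, `y`.
#' @export
mode_gallery <- function(model, mode, sd_values = c(-2, 0, 2)) {
  if (mode < 1 || mode > model$n_modes) {
    abort(paste0("`mode` must lie in 1..", model$n_modes, "."),
      class = "hipshape_error_argument"
    )
  }
  purrr::map_dfr(sd_values, function(s) {
    sc <- rep(0, model$n_modes)
    sc[mode] <- s
    p <- reconstruct_shape(model, sc)
    tibble::tibble(
      mode = mode, sd = s, point = seq_len(nrow(p)),
      x = p[, 1], y = p[, 2]
    )
  })
}
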