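# Logistic fracture-risk models and their discrimination summaries: Wald
# odds-ratio tables, AUROC with DeLong confidence intervals, and McFadden
# pseudo-R2. Model fitting itself goes through stats::glm (IRLS maximum
# likelihood); this module wraps it with the epidemiological reporting the
# analysis needs.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen case's risk score exceeds a
#' randomly chosen control's, with ties counted one-half (the Mann-Whitney
#' identity), computed from midranks.
#'
#' @param scores Numeric risk scores (higher = more case-like).
#' @param outcome Logical (or 0/1) outcome; `TRUE` = case.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, outcome) {
  y <- as.logical(outcome)
  if (anyNA(y) || anyNA(scores)) {
    abort("Missing values in scores or outcome.", class = "hipshape_error_argument")
  }
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present.", class = "hipshape_error_single_class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each case the fraction of controls it beats
# (ties half), and vice versa.
delong_placements <- function(scores, outcome) {
  y <- as.logical(outcome)
  r_all <- rank(scores, ties.method = "average")
  r_case <- rank(scores[y], ties.method = "average")
  r_ctrl <- rank(scores[!y], ties.method = "average")
  n1 <- sum(y)
  n0 <- sum(!y)
  v10 <- (r_all[y] - r_case) / n0 # per-case placements
  v01 <- 1 - (r_all[!y] - r_ctrl) / n1 # per-control placements
  list(v10 = v10, v01 = v01, n1 = n1, n0 = n0)
}

#' DeLong 95% confidence interval for AUROC
#'
#' Normal-approximation interval using the DeLong variance estimate, truncated
#' to `[0, 1]`. When the DeLong variance degenerates to zero while the AUROC
#' is not at a boundary, a percentile bootstrap (2000 resamples under a fixed
#' internal seed) is used instead.
#'
#' @inheritParams auroc
#' @param conf_level Confidence level (default 0.95).
#' @param boot_reps,boot_seed Bootstrap fallback settings.
#' @return Tibble with `auroc`, `conf_low`, `conf_high`, `se`, `method`.
#' @export
auroc_ci <- function(scores, outcome, conf_level = 0.95,
                     boot_reps = 2000, boot_seed = 20260921) {
  y <- as.logical(outcome)
  a <- auroc(scores, y)
  pl <- delong_placements(scores, y)
  if (pl$n1 < 2 || pl$n0 < 2) {
    abort("Need at least 2 subjects per class for a CI.",
      class = "hipshape_error_argument"
    )
  }
  v <- var(pl$v10) / pl$n1 + var(pl$v01) / pl$n0
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (v > 0 || a %in% c(0, 1)) {
    se <- sqrt(v)
    lo <- max(0, a - z * se)
    hi <- min(1, a + z * se)
    method <- "delong"
  } else {
    idx1 <- which(y)
    idx0 <- which(!y)
    boots <- withr::with_seed(boot_seed, vapply(seq_len(boot_reps), function(i) {
      s1 <- sample(idx1, pl$n1, replace = TRUE)
      s0 <- sample(idx0, pl$n0, replace = TRUE)
      auroc(c(scores[s1], scores[s0]), c(rep(TRUE, pl$n1), rep(FALSE, pl$n0)))
    }, numeric(1)))
    qs <- quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2))
    se <- sd(boots)
    lo <- max(0, qs[[1]])
    hi <- min(1, qs[[2]])
    method <- "bootstrap"
  }
  tibble::tibble(auroc = a, conf_low = lo, conf_high = hi, se = se, method = method)
}

#' McFadden pseudo-R2
#'
#' `1 - logLik(model) / logLik(null)` for a fitted binomial model against the
#' intercept-only model on the same outcome.
#'
#' @param fit A fitted `glm` (binomial) or `fracture_fit`.
#' @param null_fit Optional null model; defaults to the intercept-only fit on
#'   the same outcome.
#' @return Pseudo-R2 in `[0, 1)`.
#' @export
mcfadden_r2 <- function(fit, null_fit = NULL) {
  if (inherits(fit, "fracture_fit")) fit <- fit$fit
  ll <- as.numeric(logLik(fit))
  ll0 <- if (is.null(null_fit)) {
    y <- fit$y
    as.numeric(logLik(glm(y ~ 1, family = binomial())))
  } else {
    if (inherits(null_fit, "fracture_fit")) null_fit <- null_fit$fit
    as.numeric(logLik(null_fit))
  }
  if (ll0 == 0) {
    abort("Null log-likelihood is zero; pseudo-R2 undefined.",
      class = "hipshape_error_degenerate"
    )
  }
  1 - ll / ll0
}

# Detect (quasi-)complete separation from a fitted glm: fitted probabilities
# numerically at 0/1, or IRLS failing to converge.
detect_separation <- function(fit) {
  p <- fitted(fit)
  eps <- 1e-8
  !fit$converged || any(p < eps | p > 1 - eps)
}

#' Fit a logistic fracture-risk model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of a
#' binary fracture outcome on the named predictors plus adjustment
#' covariates, wrapped with the discrimination summaries used throughout the
#' analysis: the Wald odds-ratio table ([tidy()]), and AUROC with a DeLong
#' 95% CI plus McFadden pseudo-R2 ([glance()]). Predicted probabilities from
#' the full (predictors + adjustment) model feed the ROC, which is how an
#' "age- and BMI-adjusted" AUROC is obtained for a single predictor.
#'
#' @param data Data frame holding outcome, predictors and adjustment columns
#'   (e.g. the join of mode scores and subject covariates).
#' @param predictors Character vector of predictor column names.
#' @param adjust Character vector of adjustment covariates (default
#'   `c("age", "bmi")`; use `character()` for none).
#' @param outcome Name of the logical outcome column (default `"fracture"`).
#' @param ridge Optional ridge penalty (e.g. `1e-4`) applied to all
#'   non-intercept coefficients; off (`0`) by default and only needed under
#'   complete separation. Penalized fits report no Wald covariance.
#' @return An object of class `fracture_fit`.
#' @export
fit_fracture_model <- function(data, predictors, adjust = c("age", "bmi"),
                               outcome = "fracture", ridge = 0) {
  terms <- c(predictors, adjust)
  missing_cols <- setdiff(c(outcome, terms), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "hipshape_error_argument"
    )
  }
  y <- as.logical(data[[outcome]])
  if (length(unique(y)) != 2) {
    abort("Outcome must contain both cases and controls.",
      class = "hipshape_error_single_class"
    )
  }
  x <- as.matrix(data[terms])
  if (nrow(x) <= ncol(x) + 1) {
    abort("Need n > p + 1 observations.", class = "hipshape_error_argument")
  }
  constant <- apply(x, 2, function(col) sd(col) == 0)
  if (any(constant)) {
    abort(
      paste0(
        "Predictor(s) constant in this subset: ",
        paste(terms[constant], collapse = ", ")
      ),
      class = "hipshape_error_constant_predictor"
    )
  }
  qx <- qr(cbind(1, x))
  if (qx$rank < ncol(x) + 1) {
    dropped <- terms[setdiff(seq_len(ncol(x)), qx$pivot[seq_len(qx$rank)] - 1)]
    abort(
      paste0(
        "Singular design; collinear column(s): ",
        paste(dropped, collapse = ", ")
      ),
      class = "hipshape_error_singular"
    )
  }
  df <- data.frame(.y = y, x, check.names = FALSE)
  if (ridge > 0) {
    fit <- ridge_logistic(x, y, ridge)
  } else {
    fit <- suppressWarnings(glm(
      .y ~ ., data = df, family = binomial(),
      control = list(epsilon = 1e-10, maxit = 100)
    ))
    if (detect_separation(fit)) {
      abort(
        paste0(
          "Complete or quasi-complete separation detected; refit with ",
          "`ridge = 1e-4` if a penalized fit is acceptable."
        ),
        class = "hipshape_error_separation"
      )
    }
  }
  structure(
    list(
      fit = fit,
      predictors = predictors,
      adjust = adjust,
      outcome = outcome,
      n_cases = sum(y),
      n_controls = sum(!y),
      ridge = ridge,
      converged = if (ridge > 0) fit$converged else fit$converged
    ),
    class = "fracture_fit"
  )
}

# Ridge-penalized logistic fit by BFGS on the penalized log-likelihood.
# Intercept unpenalized. Returns a lightweight glm-like list.
ridge_logistic <- function(x, y, lambda) {
  xd <- cbind(`(Intercept)` = 1, x)
  nll <- function(beta) {
    eta <- as.vector(xd %*% beta)
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(beta[-1]^2) / 2
  }
  gr <- function(beta) {
    eta <- as.vector(xd %*% beta)
    g <- -as.vector(t(xd) %*% (y - plogis(eta)))
    g[-1] <- g[-1] + lambda * beta[-1]
    g
  }
  opt <- stats::optim(rep(0, ncol(xd)), nll, gr,
    method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-12)
  )
  beta <- setNames(opt$par, colnames(xd))
  eta <- as.vector(xd %*% beta)
  list(
    coefficients = beta,
    fitted.values = plogis(eta),
    y = as.numeric(y),
    converged = opt$convergence == 0,
    loglik = sum(y * eta - log1p(exp(eta))),
    penalized = TRUE
  )
}

#' @export
print.fracture_fit <- function(x, ...) {
  g <- glance(x)
  cat(
    "Logistic fracture-risk model\n",
    "  predictors: ", paste(x$predictors, collapse = ", "), "\n",
    "  adjusted for: ",
    if (length(x$adjust)) paste(x$adjust, collapse = ", ") else "(none)", "\n",
    "  cases/controls: ", x$n_cases, "/", x$n_controls, "\n",
    "  AUROC: ", sprintf("%.3f", g$auroc),
    " (95% CI ", sprintf("%.3f", g$conf_low), "-",
    sprintf("%.3f", g$conf_high), ")",
    "  pseudo-R2: ", sprintf("%.3f", g$pseudo_r2), "\n",
    sep = ""
  )
  invisible(x)
}

#' Risk scores (fitted probabilities) of a fracture model
#'
#' @param object A `fracture_fit`.
#' @param ... Unused.
#' @return Numeric vector of fitted fracture probabilities.
#' @export
risk_scores <- function(object, ...) {
  as.vector(fitted(object))
}

#' @export
fitted.fracture_fit <- function(object, ...) {
  if (isTRUE(object$fit$penalized)) object$fit$fitted.values else fitted(object$fit)
}

#' Odds-ratio table of a fracture model
#'
#' One row per model term: log-odds coefficient with Wald SE, odds ratio with
#' 95% Wald CI (`exp(beta +/- 1.96 SE)`), and two-sided Wald p-value.
#'
#' @param x A `fracture_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fracture_fit <- function(x, ...) {
  if (isTRUE(x$fit$penalized)) {
    beta <- x$fit$coefficients
    return(tibble::tibble(
      term = names(beta), estimate = unname(beta),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_,
      odds.ratio = exp(unname(beta)), conf.low = NA_real_, conf.high = NA_real_
    ))
  }
  beta <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- beta / se
  zc <- qnorm(0.975)
  tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(z),
    p.value = unname(2 * pnorm(-abs(z))),
    odds.ratio = exp(unname(beta)),
    conf.low = exp(unname(beta - zc * se)),
    conf.high = exp(unname(beta + zc * se))
  )
}

#' @rdname tidy.fracture_fit
#' @param fit A `fracture_fit`.
#' @export
odds_ratio_table <- function(fit) {
  tidy(fit)
}

#' @export
glance.fracture_fit <- function(x, ...) {
  y <- as.logical(x$fit$y)
  ci <- auroc_ci(fitted(x), y)
  tibble::tibble(
    auroc = ci$auroc, conf_low = ci$conf_low, conf_high = ci$conf_high,
    pseudo_r2 = if (isTRUE(x$fit$penalized)) NA_real_ else mcfadden_r2(x),
    n_cases = x$n_cases, n_controls = x$n_controls,
    converged = x$converged
  )
}
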