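# Model-comparison machinery: AUROC grids over predictor sets and fracture
# sites, and BMD T-score strata.

#' Default model specifications for the comparison grid
#'
#' Single predictors (the 10-mode hip-shape block, site-specific BMD, neck
#' geometry) and the pairwise shape/geometry-with-BMD combinations.
#'
#' @param n_modes Number of shape modes in the "hip shape" block.
#' @return Named list of predictor-name vectors.
#' @export
default_model_specs <- function(n_modes = 10) {
  modes <- paste0("mode", seq_len(n_modes))
  list(
    "Hip shape (modes 1-10)" = modes,
    "Femoral neck BMD" = "bmd_fn",
    "Intertrochanteric BMD" = "bmd_it",
    "Femoral neck length" = "neck_length",
    "Femoral neck width" = "neck_width",
    "Hip shape + femoral neck BMD" = c(modes, "bmd_fn"),
    "Hip shape + intertrochanteric BMD" = c(modes, "bmd_it"),
    "Neck length + femoral neck BMD" = c("neck_length", "bmd_fn"),
    "Neck length + intertrochanteric BMD" = c("neck_length", "bmd_it"),
    "Neck width + femoral neck BMD" = c("neck_width", "bmd_fn"),
    "Neck width + intertrochanteric BMD" = c("neck_width", "bmd_it")
  )
}

fracture_sets <- function(data) {
  site <- data$fracture_site
  list(
    all = rep(TRUE, nrow(data)),
    femoral_neck = !data$fracture | site == "femoral_neck",
    intertrochanteric = !data$fracture | site == "intertrochanteric"
  )
}

#' AUROC comparison grid over model specs and fracture sites
#'
#' For each model specification and each outcome set (all fractures;
#' femoral-neck fractures vs all controls; intertrochanteric fractures vs all
#' controls) fits the adjusted logistic model and reports in-sample AUROC
#' with its 95% CI and the McFadden pseudo-R2. Fractures at neither site
#' (`fracture_site == "other"`) are excluded from the site-specific columns.
#'
#' @param data Data frame with `fracture`, `fracture_site`, the predictor
#'   columns and the adjustment covariates (typically the join of
#'   [score_shapes()], [measure_geometry()] and the subject table).
#' @param specs Named list of predictor-name vectors
#'   (default [default_model_specs()]).
#' @param adjust Adjustment covariates (default age and BMI).
#' @param by_site Also compute the two site-specific columns (default TRUE
#'   when `fracture_site` is present).
#' @param on_error `"abort"` (default) propagates estimation failures such as
#'   separation or a constant predictor; `"note"` records them as NA cells
#'   with the message in a `note` column (useful for small cohorts where not
#'   every model is estimable).
#' @return Tibble with one row per model x fracture set: `model`,
#'   `fracture_set`, `n_cases`, `n_controls`, `auroc`, `conf_low`,
#'   `conf_high`, `pseudo_r2`.
#' @export
model_comparison_table <- function(data, specs = default_model_specs(),
                                   adjust = c("age", "bmi"),
                                   by_site = "fracture_site" %in% names(data),
                                   on_error = c("abort", "note")) {
  on_error <- match.arg(on_error)
  sets <- if (by_site) {
    fracture_sets(data)
  } else {
    list(all = rep(TRUE, nrow(data)))
  }
  purrr::imap_dfr(sets, function(keep, set_name) {
    sub <- data[keep, , drop = FALSE]
    if (sum(sub$fracture) == 0 || sum(!sub$fracture) == 0) {
      abort(paste0("Outcome subset `", set_name, "` has a single class."),
        class = "hipshape_error_single_class"
      )
    }
    purrr::imap_dfr(specs, function(predictors, model_name) {
      cell <- function() {
        fit <- fit_fracture_model(sub, predictors, adjust = adjust)
        g <- glance(fit)
        tibble::tibble(
          model = model_name, fracture_set = set_name,
          n_cases = g$n_cases, n_controls = g$n_controls,
          auroc = g$auroc, conf_low = g$conf_low, conf_high = g$conf_high,
          pseudo_r2 = g$pseudo_r2, note = NA_character_
        )
      }
      if (on_error == "abort") {
        cell()
      } else {
        tryCatch(cell(), error = function(e) {
          tibble::tibble(
            model = model_name, fracture_set = set_name,
            n_cases = sum(sub$fracture), n_controls = sum(!sub$fracture),
            auroc = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
            pseudo_r2 = NA_real_, note = conditionMessage(e)
          )
        })
      }
    })
  })
}

#' Assign femoral-neck T-score strata
#'
#' Normal: T > -1; osteopenic: -2.5 <= T <= -1; osteoporotic: T < -2.5.
#' The boundary values -1 and -2.5 belong to the osteopenic stratum. The
#' three rules partition the real line.
#'
#' @param tscore Numeric femoral-neck T-scores.
#' @return Factor with levels `normal`, `osteopenic`, `osteoporotic`.
#' @export
tscore_stratum <- function(tscore) {
  out <- ifelse(tscore > -1, "normal",
    ifelse(tscore >= -2.5, "osteopenic", "osteoporotic")
  )
  factor(out, levels = c("normal", "osteopenic", "osteoporotic"))
}

#' AUROC comparison within T-score strata
#'
#' Partitions subjects into BMD strata by femoral-neck T-score and runs the
#' model-comparison grid within each stratum. Strata (or cells) where a model
#' cannot be estimated — an empty stratum, a single-class outcome, or a
#' constant predictor — are reported with `NA` values and a `note` rather
#' than failing.
#'
#' @inheritParams model_comparison_table
#' @param tscore Name of the T-score column (default `"fn_tscore"`).
#' @param by_site Site-specific columns within strata (default `FALSE`:
#'   strata are small, so the all-fractures column is the default).
#' @return Tibble of per-stratum results with per-stratum case counts and
#'   percentages (`case_pct`, nearest integer).
#' @export
stratified_auroc <- function(data, specs = default_model_specs(),
                             adjust = c("age", "bmi"),
                             tscore = "fn_tscore", by_site = FALSE) {
  if (!tscore %in% names(data)) {
    abort(paste0("T-score column `", tscore, "` not found."),
      class = "hipshape_error_argument"
    )
  }
  data <- data[!is.na(data[[tscore]]), , drop = FALSE]
  strata <- tscore_stratum(data[[tscore]])
  purrr::map_dfr(levels(strata), function(st) {
    sub <- data[strata == st, , drop = FALSE]
    base <- tibble::tibble(
      stratum = st,
      n = nrow(sub),
      n_cases = sum(sub$fracture),
      case_pct = if (nrow(sub) > 0) case_percent(sum(sub$fracture), nrow(sub)) else NA_real_
    )
    if (nrow(sub) == 0 || length(unique(sub$fracture)) < 2) {
      return(dplyr::bind_cols(
        base,
        tibble::tibble(
          model = NA_character_, fracture_set = NA_character_,
          auroc = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
          pseudo_r2 = NA_real_,
          note = "not estimable: empty stratum or single-class outcome"
        )
      ))
    }
    purrr::imap_dfr(specs, function(predictors, model_name) {
      res <- tryCatch(
        {
          tab <- model_comparison_table(sub,
            specs = setNames(list(predictors), model_name),
            adjust = adjust, by_site = by_site
          )
          dplyr::mutate(
            dplyr::select(
              tab, "model", "fracture_set", "auroc",
              "conf_low", "conf_high", "pseudo_r2"
            ),
            note = NA_character_
          )
        },
        error = function(e) {
          tibble::tibble(
            model = model_name, fracture_set = NA_character_,
            auroc = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
            pseudo_r2 = NA_real_, note = conditionMessage(e)
          )
        }
      )
      dplyr::bind_cols(base[rep(1, nrow(res)), ], res)
    })
  })
}
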