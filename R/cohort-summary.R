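# Baseline case/control cohort description: group means +/- SD for continuous
# variables with Welch two-sample t tests, counts (%) with Pearson chi-square
# tests for categoricals.

#' Case-to-control ratio
#'
#' @param n_cases,n_controls Group sizes.
#' @return Controls per case, rounded to 2 decimals (half-up).
#' @export
#' @examples
#' case_control_ratio(168, 231) # 1.38
case_control_ratio <- function(n_cases, n_controls) {
  if (!is.numeric(n_cases) || n_cases <= 0) {
    abort("`n_cases` must be positive.", class = "hipshape_error_argument")
  }
  round_half_up(n_controls / n_cases, 2)
}

#' Summarize a case/control cohort
#'
#' Builds a baseline-characteristics table: per-group mean +/- SD and a Welch
#' two-sample t test for continuous variables; per-group count (%) and a
#' Pearson chi-square test (no continuity correction) for binary/categorical
#' variables. Welch's unequal-variance t test is used as the safer default
#' for "Student's t" style group comparisons. Variables that are constant in
#' both groups get `p_value = NA` and `test = "not-applicable"` rather than
#' failing.
#'
#' @param subjects Subject tibble including the grouping column.
#' @param continuous,categorical Character vectors of column names; by
#'   default numeric columns are treated as continuous and logical columns as
#'   categorical (excluding the group column and `subject_id`).
#' @param group Name of the logical grouping column (default `"fracture"`;
#'   `TRUE` = case).
#' @return A tibble with one row per variable: group summaries (numeric and
#'   formatted), test statistic, p-value and test name.
#' @export
summarize_cohort <- function(subjects, continuous = NULL, categorical = NULL,
                             group = "fracture") {
  if (!group %in% names(subjects)) {
    abort(paste0("Grouping column `", group, "` not found."),
      class = "hipshape_error_argument"
    )
  }
  g <- as.logical(subjects[[group]])
  if (anyNA(g) || length(unique(g)) != 2) {
    abort("Grouping column must be binary with both groups present.",
      class = "hipshape_error_argument"
    )
  }
  if (sum(g) < 2 || sum(!g) < 2) {
    abort("Each group needs at least 2 subjects.",
      class = "hipshape_error_argument"
    )
  }
  candidates <- setdiff(names(subjects), c("subject_id", group, "fracture_site"))
  if (is.null(continuous)) {
    continuous <- candidates[vapply(subjects[candidates], is.numeric, logical(1))]
  }
  if (is.null(categorical)) {
    categorical <- candidates[vapply(subjects[candidates], is.logical, logical(1))]
  }

  cont_rows <- purrr::map(continuous, function(v) {
    xc <- subjects[[v]][g]
    xk <- subjects[[v]][!g]
    constant <- sd(c(xc, xk)) == 0 || (sd(xc) == 0 && sd(xk) == 0)
    p <- NA_real_
    statistic <- NA_real_
    test <- "not-applicable"
    if (!constant) {
      tt <- t.test(xc, xk, var.equal = FALSE)
      p <- tt$p.value
      statistic <- unname(tt$statistic)
      test <- "Welch t"
    }
    tibble::tibble(
      variable = v, type = "continuous",
      case_mean = mean(xc), case_sd = sd(xc),
      control_mean = mean(xk), control_sd = sd(xk),
      case_n = NA_integer_, control_n = NA_integer_,
      case_summary = paste0(
        round_half_up(mean(xc), 1), " ± ", round_half_up(sd(xc), 1)
      ),
      control_summary = paste0(
        round_half_up(mean(xk), 1), " ± ", round_half_up(sd(xk), 1)
      ),
      statistic = statistic, p_value = p, test = test
    )
  })

  cat_rows <- purrr::map(categorical, function(v) {
    xc <- as.logical(subjects[[v]][g])
    xk <- as.logical(subjects[[v]][!g])
    tab <- rbind(c(sum(xc), sum(!xc)), c(sum(xk), sum(!xk)))
    constant <- any(colSums(tab) == 0)
    p <- NA_real_
    statistic <- NA_real_
    test <- "not-applicable"
    if (!constant) {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      p <- ct$p.value
      statistic <- unname(ct$statistic)
      test <- "Pearson chi-square"
    }
    tibble::tibble(
      variable = v, type = "categorical",
      case_mean = NA_real_, case_sd = NA_real_,
      control_mean = NA_real_, control_sd = NA_real_,
      case_n = sum(xc), control_n = sum(xk),
      case_summary = paste0(
        sum(xc), " (", round_half_up(100 * mean(xc), 1), "%)"
      ),
      control_summary = paste0(
        sum(xk), " (", round_half_up(100 * mean(xk), 1), "%)"
      ),
      statistic = statistic, p_value = p, test = test
    )
  })

  out <- dplyr::bind_rows(c(cont_rows, cat_rows))
  attr(out, "n_cases") <- sum(g)
  attr(out, "n_controls") <- sum(!g)
  out
}

#' Percentage of cases in a stratum
#'
#' @param n_cases,n_total Case count and stratum size.
#' @return Percentage rounded to the nearest integer (half-up).
#' @export
#' @examples
#' case_percent(9, 44) # 20
case_percent <- function(n_cases, n_total) {
  round_half_up(100 * n_cases / n_total, 0)
}
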