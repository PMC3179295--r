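# Landmark outline and covariate-table input/output.
#
# Two landmark dialects are supported:
#   * CSV — one row per subject: subject_id, x1, y1, ..., xk, yk (header
#     required); flat and spreadsheet-safe.
#   * TPS — the de-facto landmark interchange format: "LM=k", k coordinate
#     lines, "ID=subject", optional "SCALE=" line.
#
# Coordinates use the mathematical convention (x rightward, y upward). Files
# digitized with an image-origin (row-down) convention can be flipped on
# import with `flip_y = TRUE`. When `pixel_spacing_mm` is supplied (or a TPS
# SCALE line is present) coordinates are converted from pixels to mm.

#' Pixel pitch from scanner resolution
#'
#' Converts a digitizer resolution in dots per inch to the physical spacing of
#' one pixel in millimetres, reported to three decimals (half-up). A 150-dpi
#' radiograph scan corresponds to 0.169 mm pixels.
#'
#' @param dpi Scanner resolution in dots per inch (positive scalar).
#' @return Pixel spacing in mm, rounded to 3 decimals.
#' @export
#' @examples
#' pixel_pitch_mm(150) # 0.169
pixel_pitch_mm <- function(dpi) {
  check_positive_scalar(dpi, "dpi")
  round_half_up(25.4 / dpi, 3)
}

#' Read landmark outlines
#'
#' @param path Path to a landmark file.
#' @param format `"csv"` or `"tps"` (see file-level notes for the dialects).
#' @param pixel_spacing_mm Optional positive scalar; when given, coordinates
#'   are multiplied by it (pixels to mm). When absent, coordinates are taken
#'   to be in mm already (a TPS `SCALE=` line is honoured the same way).
#' @param flip_y Negate y on import (for image-origin files).
#' @return A tibble with columns `subject_id`, `point`, `x`, `y` (mm).
#' @export
read_landmarks <- function(path, format = c("csv", "tps"),
                           pixel_spacing_mm = NULL, flip_y = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("Landmark file not found: ", path),
      class = "hipshape_error_io"
    )
  }
  if (!is.null(pixel_spacing_mm)) {
    check_positive_scalar(pixel_spacing_mm, "pixel_spacing_mm")
  }
  lm <- switch(format,
    csv = read_landmarks_csv(path),
    tps = read_landmarks_tps(path)
  )
  scale <- pixel_spacing_mm %||% attr(lm, "tps_scale") %||% 1
  lm$x <- lm$x * scale
  lm$y <- (if (flip_y) -1 else 1) * lm$y * scale
  attr(lm, "tps_scale") <- NULL
  if (anyDuplicated(lm[c("subject_id", "point")])) {
    abort("Duplicate subject ids in landmark file.",
      class = "hipshape_error_duplicate_ids"
    )
  }
  validate_landmarks(lm)
  lm
}

read_landmarks_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(raw)[1], "subject_id")) {
    abort("Landmark CSV must have a header starting with `subject_id`.",
      class = "hipshape_error_io"
    )
  }
  coord_names <- names(raw)[-1]
  k <- length(coord_names) / 2
  expected <- as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
  if (k != floor(k) || !identical(coord_names, expected)) {
    abort("Landmark CSV columns must be subject_id, x1, y1, ..., xk, yk.",
      class = "hipshape_error_io"
    )
  }
  wide_na <- !stats::complete.cases(raw)
  if (any(wide_na)) {
    abort(
      paste0(
        "Missing coordinates (interpreted as unequal point counts) for ",
        "subject(s): ", paste(raw$subject_id[wide_na], collapse = ", ")
      ),
      class = "hipshape_error_mixed_k"
    )
  }
  m <- as.matrix(raw[, -1])
  rownames(m) <- raw$subject_id
  landmark_tibble(m)
}

read_landmarks_tps <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != ""]
  i <- 1
  out <- list()
  scales <- numeric()
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      abort(paste0("TPS parse error at line ", i, ": expected 'LM=' record."),
        class = "hipshape_error_io"
      )
    }
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i], ignore.case = TRUE))
    coords <- lines[i + seq_len(k)]
    xy <- suppressWarnings(lapply(strsplit(coords, "\\s+"), as.numeric))
    if (any(vapply(xy, function(v) length(v) != 2 || anyNA(v), logical(1)))) {
      abort(paste0("TPS parse error near line ", i + 1, ": bad coordinate row."),
        class = "hipshape_error_io"
      )
    }
    i <- i + k + 1
    id <- NA_character_
    scale <- NA_real_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i], ignore.case = TRUE)) {
      if (grepl("^ID\\s*=", lines[i], ignore.case = TRUE)) {
        id <- sub("^ID\\s*=\\s*", "", lines[i], ignore.case = TRUE)
      } else if (grepl("^SCALE\\s*=", lines[i], ignore.case = TRUE)) {
        scale <- as.numeric(sub("^SCALE\\s*=\\s*", "", lines[i], ignore.case = TRUE))
      }
      i <- i + 1
    }
    if (is.na(id)) id <- paste0("s", length(out) + 1)
    p <- do.call(rbind, xy)
    out[[length(out) + 1]] <- tibble::tibble(
      subject_id = id, point = seq_len(k), x = p[, 1], y = p[, 2]
    )
    scales <- c(scales, scale)
  }
  lm <- dplyr::bind_rows(out)
  if (!all(is.na(scales))) {
    u <- unique(scales[!is.na(scales)])
    if (length(u) == 1 && all(!is.na(scales))) attr(lm, "tps_scale") <- u
  }
  lm
}

#' Write landmark outlines
#'
#' @inheritParams read_landmarks
#' @param landmarks Tidy landmark table (`subject_id`, `point`, `x`, `y`).
#' @param digits Coordinate formatting precision for the TPS dialect.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, format = c("csv", "tps"),
                            digits = 6) {
  format <- match.arg(format)
  k <- validate_landmarks(landmarks)
  m <- landmark_matrix(landmarks)
  if (format == "csv") {
    df <- tibble::as_tibble(m, .name_repair = "minimal")
    names(df) <- as.vector(rbind(paste0("x", seq_len(k)), paste0("y", seq_len(k))))
    df <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(m)), df)
    readr::write_csv(df, path, progress = FALSE)
  } else {
    fmt <- paste0("%.", digits, "f")
    blocks <- vapply(seq_len(nrow(m)), function(i) {
      p <- points_from_vec(m[i, ])
      paste(
        c(
          paste0("LM=", k),
          paste(sprintf(fmt, p[, 1]), sprintf(fmt, p[, 2])),
          paste0("ID=", rownames(m)[i])
        ),
        collapse = "\n"
      )
    }, character(1))
    writeLines(paste(blocks, collapse = "\n"), path)
  }
  invisible(path)
}

#' Apply the image-acceptability filter
#'
#' Radiographs on which the greater and lesser trochanters are not fully
#' visualized are excluded before shape modeling. The filter takes a
#' per-subject acceptability flag and returns the retained outlines together
#' with an exclusion report.
#'
#' @param landmarks Tidy landmark table.
#' @param acceptable Either a logical vector named by subject id, or a data
#'   frame with columns `subject_id` and `acceptable`. If `NULL`, an
#'   `acceptable` column in `landmarks` is used.
#' @return A list with `kept` (filtered landmark tibble) and `report`
#'   (one-row tibble: `n_total`, `n_kept`, `n_excluded`, `pct_excluded` —
#'   percentage to 1 decimal, half-up).
#' @export
#' @examples
#' lm <- landmark_tibble(matrix(rnorm(5 * 8), nrow = 5))
#' filter_acceptable(lm, setNames(c(TRUE, TRUE, FALSE, TRUE, TRUE),
#'   unique(lm$subject_id)))$report
filter_acceptable <- function(landmarks, acceptable = NULL) {
  if (nrow(landmarks) == 0) {
    abort("Empty cohort.", class = "hipshape_error_empty_cohort")
  }
  validate_landmarks(landmarks)
  ids <- unique(landmarks$subject_id)
  if (is.null(acceptable)) {
    if (!"acceptable" %in% names(landmarks)) {
      abort("No `acceptable` flag supplied or present in `landmarks`.",
        class = "hipshape_error_argument"
      )
    }
    flag_tbl <- dplyr::distinct(landmarks, .data$subject_id, .data$acceptable)
    flags <- setNames(flag_tbl$acceptable, flag_tbl$subject_id)
  } else if (is.data.frame(acceptable)) {
    flags <- setNames(acceptable$acceptable, acceptable$subject_id)
  } else {
    flags <- acceptable
  }
  if (!all(ids %in% names(flags)) || anyNA(flags[ids])) {
    abort("`acceptable` must provide a non-missing flag for every subject.",
      class = "hipshape_error_argument"
    )
  }
  keep_ids <- ids[flags[ids]]
  n_total <- length(ids)
  n_excluded <- n_total - length(keep_ids)
  list(
    kept = dplyr::filter(landmarks, .data$subject_id %in% keep_ids),
    report = tibble::tibble(
      n_total = n_total,
      n_kept = length(keep_ids),
      n_excluded = n_excluded,
      pct_excluded = round_half_up(100 * n_excluded / n_total, 1)
    )
  )
}

subject_site_levels <- c("none", "femoral_neck", "intertrochanteric", "other")

#' Read a subject covariate table
#'
#' Expected columns (documented contract): `subject_id`, `age` (years),
#' `bmi` (kg/m2), optionally `weight` (kg), `height` (cm), `bmd_fn`,
#' `bmd_it`, `bmd_th` (g/cm2), `fn_tscore`, `fracture` (logical/0-1),
#' `fracture_site` (one of `none`, `femoral_neck`, `intertrochanteric`,
#' `other`).
#'
#' @param path CSV path.
#' @return Validated tibble of subject records.
#' @export
read_subjects <- function(path) {
  validate_subjects(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Write a subject covariate table
#'
#' @param subjects Subject tibble (see [read_subjects()] for the contract).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  readr::write_csv(subjects, path, progress = FALSE)
  invisible(path)
}

#' Validate subject records
#'
#' Checks the covariate-table invariants: unique ids, binary fracture status,
#' `fracture == FALSE` implying site `none`, positive BMD values.
#'
#' @inheritParams write_subjects
#' @return The validated tibble (fracture as logical, site as factor).
#' @export
validate_subjects <- function(subjects) {
  if (!"subject_id" %in% names(subjects)) {
    abort("Subject table needs a `subject_id` column.",
      class = "hipshape_error_subjects"
    )
  }
  if (anyDuplicated(subjects$subject_id)) {
    abort("Duplicate subject ids in covariate table.",
      class = "hipshape_error_subjects"
    )
  }
  if ("fracture" %in% names(subjects)) {
    subjects$fracture <- as.logical(subjects$fracture)
    if (anyNA(subjects$fracture)) {
      abort("`fracture` must be logical or 0/1 with no missing values.",
        class = "hipshape_error_subjects"
      )
    }
  }
  if ("fracture_site" %in% names(subjects)) {
    bad_site <- !subjects$fracture_site %in% subject_site_levels
    if (any(bad_site)) {
      abort(
        paste0(
          "Unknown fracture_site value(s): ",
          paste(unique(subjects$fracture_site[bad_site]), collapse = ", ")
        ),
        class = "hipshape_error_subjects"
      )
    }
    subjects$fracture_site <- factor(subjects$fracture_site,
      levels = subject_site_levels
    )
    if ("fracture" %in% names(subjects)) {
      inconsistent <- !subjects$fracture & subjects$fracture_site != "none"
      if (any(inconsistent)) {
        abort(
          paste0(
            "Controls must have fracture_site 'none'; offending subject(s): ",
            paste(subjects$subject_id[inconsistent], collapse = ", ")
          ),
          class = "hipshape_error_subjects"
        )
      }
    }
  }
  for (col in intersect(c("bmd_fn", "bmd_it", "bmd_th"), names(subjects))) {
    if (any(subjects[[col]] <= 0, na.rm = TRUE)) {
      abort(paste0("`", col, "` must be positive."),
        class = "hipshape_error_subjects"
      )
    }
  }
  tibble::as_tibble(subjects)
}
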