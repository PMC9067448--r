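#' Load a per-patient, per-artery deviation table
#'
#' Reads the wide deviation table (one row per patient, 18 columns
#' `L_<artery>` / `R_<artery>`) in which each cell is a deviation in mm, an
#' em-dash / hyphen, or blank -- the latter two meaning the artery was not
#' visualized. The packaged fixture transcribing the study's measured
#' deviations ships as `system.file("extdata", "table2_deviations.csv",
#' package = "arterymap")`.
#'
#' @param path CSV path.
#' @return Tidy tibble of deviation records: `patient`, `side`, `artery`,
#'   `visualized`, `deviation_mm` (NA when not visualized).
#' @export
load_deviation_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  expected <- c(paste0("L_", artery_order()), paste0("R_", artery_order()))
  if (!"patient" %in% names(df) || !all(expected %in% names(df))) {
    am_stop(sprintf("%s: expected columns patient, %s", path,
                    paste(expected, collapse = ", ")),
            "arterymap_format_error")
  }
  long <- df |>
    tidyr::pivot_longer(dplyr::all_of(expected), names_to = "column",
                        values_to = "cell") |>
    tidyr::separate_wider_delim("column", "_", names = c("side_code", "artery")) |>
    dplyr::mutate(side = ifelse(.data$side_code == "L", "left", "right"),
                  patient = as.integer(.data$patient))
  missing_cell <- is.na(long$cell) | long$cell %in% c("", "—", "–", "-")
  num <- suppressWarnings(as.numeric(long$cell))
  bad <- !missing_cell & is.na(num)
  if (any(bad)) {
    b <- long[which(bad)[1], ]
    am_stop(sprintf("%s: cannot parse cell '%s' (patient %s, %s %s)",
                    path, b$cell, b$patient, b$side, b$artery),
            "arterymap_parse_error")
  }
  if (any(num[!missing_cell] < 0)) {
    am_stop(sprintf("%s: negative deviation encountered", path),
            "arterymap_parse_error")
  }
  long |>
    dplyr::mutate(visualized = !missing_cell,
                  deviation_mm = ifelse(missing_cell, NA_real_, num)) |>
    dplyr::select("patient", "side", "artery", "visualized", "deviation_mm") |>
    dplyr::arrange(.data$patient, match(.data$side, c("left", "right")),
                   match(.data$artery, artery_order()))
}

#' Path of the packaged deviation fixture
#' @export
deviation_fixture_path <- function() {
  system.file("extdata", "table2_deviations.csv", package = "arterymap")
}

group_sd <- function(x) if (length(x) <= 1L) 0 else stats::sd(x)

#' Grouped deviation statistics
#'
#' Per artery-and-side group (18 groups) and per bilateral artery (9
#' groups), over visualized records only: n, mean, maximum, minimum and
#' sample standard deviation (denominator n-1; groups of size <= 1 report
#' SD 0). The overall mean and SD are the unweighted means of the 18 group
#' means and group SDs -- the aggregation used in the study's summary table;
#' `aggregate = "pooled"` instead pools all records.
#'
#' @param records Tidy records from [load_deviation_table()] or
#'   [evaluate_projection_accuracy()].
#' @param aggregate `"group_mean"` (default) or `"pooled"`.
#' @return An object of class `accuracy_summary` with tibbles `per_side`
#'   (18 rows) and `bilateral` (9 rows) plus the `overall` list
#'   (mean_mm, sd_mm, max_mm, min_mm, n).
#' @export
group_statistics <- function(records, aggregate = c("group_mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  if (!is.data.frame(records) || nrow(records) == 0) {
    am_stop("`records` must be a non-empty data frame", "arterymap_argument_error")
  }
  vis <- dplyr::filter(records, .data$visualized)
  frame <- artery_labels()
  per_side <- frame |>
    dplyr::left_join(
      vis |>
        dplyr::group_by(.data$artery, .data$side) |>
        dplyr::summarise(n = dplyr::n(),
                         mean_mm = mean(.data$deviation_mm),
                         max_mm = max(.data$deviation_mm),
                         min_mm = min(.data$deviation_mm),
                         sd_mm = group_sd(.data$deviation_mm),
                         .groups = "drop"),
      by = c("artery", "side")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  sd_mm = ifelse(.data$n <= 1, 0, .data$sd_mm))
  bilateral <- vis |>
    dplyr::group_by(.data$artery) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_mm = mean(.data$deviation_mm),
                     max_mm = max(.data$deviation_mm),
                     min_mm = min(.data$deviation_mm),
                     sd_mm = group_sd(.data$deviation_mm),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$artery, artery_order()))
  overall <- if (aggregate == "group_mean") {
    list(mean_mm = mean(per_side$mean_mm, na.rm = TRUE),
         sd_mm = mean(per_side$sd_mm, na.rm = TRUE),
         max_mm = max(vis$deviation_mm),
         min_mm = min(vis$deviation_mm),
         n = nrow(vis))
  } else {
    list(mean_mm = mean(vis$deviation_mm),
         sd_mm = group_sd(vis$deviation_mm),
         max_mm = max(vis$deviation_mm),
         min_mm = min(vis$deviation_mm),
         n = nrow(vis))
  }
  structure(list(per_side = per_side, bilateral = bilateral,
                 overall = overall, aggregate = aggregate),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("<accuracy_summary> ", x$overall$n, " visualized arteries; overall mean ",
      sprintf("%.2f", x$overall$mean_mm), " mm (SD ",
      sprintf("%.2f", x$overall$sd_mm), " mm), max ",
      x$overall$max_mm, " mm\n", sep = "")
  print(x$per_side, n = 18)
  invisible(x)
}

#' @export
tidy.accuracy_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$per_side, grouping = "per_side"),
    dplyr::mutate(x$bilateral, side = "both", grouping = "bilateral")
  ) |>
    dplyr::select("grouping", "artery", "side", "n", "mean_mm", "max_mm",
                  "min_mm", "sd_mm")
}

#' @export
glance.accuracy_summary <- function(x, ...) {
  tibble::tibble(n_visualized = x$overall$n,
                 mean_mm = x$overall$mean_mm,
                 sd_mm = x$overall$sd_mm,
                 max_mm = x$overall$max_mm,
                 min_mm = x$overall$min_mm,
                 aggregate = x$aggregate)
}

#' Visualization counts and percentages per artery
#'
#' How often each artery was visualized, split by side, with the bilateral
#' percentage out of `2 * n_subjects` to one decimal.
#'
#' @param records Tidy records (as from [load_deviation_table()]).
#' @param n_subjects Defaults to the number of distinct patients.
#' @return Tibble (artery, left, right, total, percentage).
#' @export
visualization_percentages <- function(records, n_subjects = NULL) {
  if (is.null(n_subjects)) n_subjects <- dplyr::n_distinct(records$patient)
  records |>
    dplyr::filter(.data$visualized) |>
    dplyr::transmute(subject = .data$patient, artery = .data$artery,
                     side = .data$side) |>
    tally_visualization(n_subjects = n_subjects)
}

#' Labial-artery sensitivity with brace patients excluded
#'
#' Dental braces cause metal artifacts that suppress the labial arteries on
#' MRA. This recomputes the visualization percentage of the inferior and
#' superior labial arteries after excluding the affected patients from the
#' denominator (assuming, as in the study, that every artifacted labial
#' artery belongs to a brace patient): denominator
#' `2 * (n_subjects - excluded_patient_count)`.
#'
#' @param records Tidy records.
#' @param excluded_patient_count Number of patients excluded.
#' @param n_subjects Defaults to the number of distinct patients.
#' @return Tibble (artery, n_visualized, denominator, percentage).
#' @export
recompute_excluding_braces <- function(records, excluded_patient_count = 7L,
                                       n_subjects = NULL) {
  if (is.null(n_subjects)) n_subjects <- dplyr::n_distinct(records$patient)
  if (excluded_patient_count < 0 || excluded_patient_count >= n_subjects) {
    am_stop("excluded patient count must lie in [0, n_subjects)",
            "arterymap_argument_error")
  }
  denom <- 2L * (n_subjects - excluded_patient_count)
  records |>
    dplyr::filter(.data$visualized, .data$artery %in% c("IL", "SL")) |>
    dplyr::count(.data$artery, name = "n_visualized") |>
    dplyr::right_join(tibble::tibble(artery = c("IL", "SL")), by = "artery") |>
    dplyr::mutate(n_visualized = dplyr::coalesce(.data$n_visualized, 0L),
                  denominator = as.integer(denom),
                  percentage = round(100 * .data$n_visualized / denom, 1)) |>
    dplyr::arrange(match(.data$artery, artery_order()))
}

point_segment_dist2 <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  wx <- px - ax; wy <- py - ay
  len2 <- vx^2 + vy^2
  t <- ifelse(len2 > 0, pmin(pmax((wx * vx + wy * vy) / len2, 0), 1), 0)
  (wx - t * vx)^2 + (wy - t * vy)^2
}

#' Deviation of projected artery curves from marked truth locations
#'
#' For each truth mark, the deviation is the distance to the nearest point
#' of any same-labeled projected curve, converted from pixels to mm. Marks
#' whose label has no projected curve are recorded as not visualized.
#'
#' @param projected_curves Tibble (label, curve, u, v) as in the `overlay`
#'   of [register_model_to_view()], pixel coordinates.
#' @param truth_marks Tibble (label, u, v) of marked locations (px).
#' @param pixel_to_mm Pixel size in mm (> 0).
#' @param patient_id Optional patient id recorded on each row.
#' @return Tidy deviation records: `patient`, `side`, `artery`,
#'   `visualized`, `deviation_mm`.
#' @export
evaluate_projection_accuracy <- function(projected_curves, truth_marks,
                                         pixel_to_mm = 1, patient_id = NA_integer_) {
  if (!is.numeric(pixel_to_mm) || pixel_to_mm <= 0) {
    am_stop("`pixel_to_mm` must be positive", "arterymap_argument_error")
  }
  if (nrow(truth_marks) == 0) {
    am_stop("at least one truth mark is required", "arterymap_argument_error")
  }
  purrr::pmap_dfr(truth_marks, function(label, u, v, ...) {
    cur <- dplyr::filter(projected_curves, .data$label == !!label)
    parts <- strsplit(label, "_", fixed = TRUE)[[1]]
    base <- tibble::tibble(patient = patient_id,
                           side = if (length(parts) > 1) parts[2] else NA_character_,
                           artery = parts[1])
    if (nrow(cur) == 0) {
      return(dplyr::mutate(base, visualized = FALSE, deviation_mm = NA_real_))
    }
    d2 <- Inf
    for (cid in unique(cur$curve)) {
      cc <- dplyr::filter(cur, .data$curve == cid)
      if (nrow(cc) == 1) {
        d2 <- min(d2, (cc$u - u)^2 + (cc$v - v)^2)
      } else {
        n <- nrow(cc)
        d2 <- min(d2, point_segment_dist2(u, v, cc$u[-n], cc$v[-n],
                                          cc$u[-1], cc$v[-1]))
      }
    }
    dplyr::mutate(base, visualized = TRUE,
                  deviation_mm = sqrt(d2) * pixel_to_mm)
  })
}
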