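fixture_records <- function() load_deviation_table(deviation_fixture_path())

test_that("the packaged deviation table parses to the documented totals", {
  rec <- fixture_records()
  expect_identical(nrow(rec), 360L)
  expect_identical(sum(rec$visualized), 216L)
  expect_identical(sum(rec$visualized & rec$side == "left"), 113L)
  expect_identical(sum(rec$visualized & rec$side == "right"), 103L)
  # the one blank cell: patient 13, right angular
  blank <- rec[rec$patient == 13 & rec$side == "right" & rec$artery == "Ang", ]
  expect_false(blank$visualized)
})

test_that("malformed cells raise a parse error naming the location", {
  p <- withr::local_tempfile(fileext = ".csv")
  lines <- readLines(deviation_fixture_path())
  lines[3] <- sub("^2,2", "2,x", lines[3])
  writeLines(lines, p)
  err <- expect_error(load_deviation_table(p), class = "arterymap_parse_error")
  expect_match(conditionMessage(err), "patient 2")
  expect_match(conditionMessage(err), "Fa")
})

test_that("group statistics reproduce the per-group and overall values", {
  s <- group_statistics(fixture_records())
  fa_l <- s$per_side[s$per_side$artery == "Fa" & s$per_side$side == "left", ]
  expect_identical(fa_l$n, 15L)
  expect_identical(round_half_up(fa_l$mean_mm), 0.73)
  expect_identical(round_half_up(fa_l$sd_mm), 1.28)
  expect_identical(round_half_up(s$overall$mean_mm), 0.31)
  expect_identical(round_half_up(s$overall$sd_mm), 0.66)
  expect_identical(s$overall$max_mm, 5)
  # the 5 mm maximum occurs in a left superficial temporal record
  rec <- fixture_records()
  worst <- rec[rec$visualized & rec$deviation_mm == 5, ]
  expect_identical(worst$side, "left")
  expect_identical(worst$artery, "ST")
  # pooled aggregation is exposed but differs from the group-mean aggregation
  pooled <- group_statistics(fixture_records(), aggregate = "pooled")
  expect_false(round_half_up(pooled$overall$sd_mm) == 0.66)
})

test_that("degenerate groups report SD 0 and empty input errors", {
  one <- tibble::tibble(patient = 1L, side = "left", artery = "Fa",
                        visualized = TRUE, deviation_mm = 2)
  s <- group_statistics(one)
  g <- s$per_side[s$per_side$artery == "Fa" & s$per_side$side == "left", ]
  expect_identical(g$mean_mm, 2)
  expect_identical(g$sd_mm, 0)
  expect_error(group_statistics(tibble::tibble()),
               class = "arterymap_argument_error")
})

test_that("statistics are invariant to record order", {
  rec <- fixture_records()
  set.seed(8)
  s1 <- glance(group_statistics(rec))
  s2 <- glance(group_statistics(rec[sample.int(nrow(rec)), ]))
  expect_equal(s1, s2)
})

test_that("tidy/glance expose the summary as tibbles", {
  s <- group_statistics(fixture_records())
  td <- tidy(s)
  expect_identical(nrow(td), 27L)  # 18 per-side + 9 bilateral
  expect_true(all(c("grouping", "artery", "side", "mean_mm") %in% names(td)))
  gl <- glance(s)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_visualized, 216L)
})

test_that("visualization percentages match the published counts", {
  vp <- visualization_percentages(fixture_records())
  want <- tibble::tribble(
    ~artery, ~left, ~right, ~total, ~percentage,
    "Fa", 15L, 15L, 30L, 75.0,
    "IL", 5L, 2L, 7L, 17.5,
    "SL", 10L, 8L, 18L, 45.0,
    "Ang", 15L, 18L, 33L, 82.5,
    "LN", 14L, 11L, 25L, 62.5,
    "DN", 4L, 5L, 9L, 22.5,
    "STr", 19L, 18L, 37L, 92.5,
    "SO", 11L, 6L, 17L, 42.5,
    "ST", 20L, 20L, 40L, 100.0
  )
  expect_equal(as.data.frame(vp), as.data.frame(want))
  all_present <- tidyr::expand_grid(patient = 1:4,
                                    side = c("left", "right"),
                                    artery = artery_order()) |>
    dplyr::mutate(visualized = TRUE, deviation_mm = 0)
  expect_true(all(visualization_percentages(all_present)$percentage == 100))
})

test_that("brace exclusion adjusts the labial denominators", {
  rec <- fixture_records()
  adj <- recompute_excluding_braces(rec, excluded_patient_count = 7)
  expect_identical(adj$denominator, c(26L, 26L))
  expect_identical(adj$percentage[adj$artery == "IL"], 26.9)
  expect_identical(adj$percentage[adj$artery == "SL"], 69.2)
  none <- recompute_excluding_braces(rec, excluded_patient_count = 0)
  expect_identical(none$percentage[none$artery == "IL"], 17.5)
  expect_identical(none$percentage[none$artery == "SL"], 45.0)
  expect_error(recompute_excluding_braces(rec, excluded_patient_count = 20),
               class = "arterymap_argument_error")
})

test_that("projection deviations use nearest-point distance with unit conversion", {
  curve <- tibble::tibble(label = "Fa_left", curve = 1L,
                          u = seq(0, 100, by = 1), v = 50)
  marks <- tibble::tibble(label = c("Fa_left", "Fa_left", "ST_left"),
                          u = c(30, 40, 10), v = c(50, 53, 50))
  recs <- evaluate_projection_accuracy(curve, marks, pixel_to_mm = 0.5)
  expect_identical(recs$deviation_mm[1], 0)
  expect_identical(recs$deviation_mm[2], 1.5)  # 3 px perpendicular * 0.5 mm
  expect_false(recs$visualized[3])             # no ST curve present
  expect_error(evaluate_projection_accuracy(curve, marks, pixel_to_mm = 0),
               class = "arterymap_argument_error")
  expect_error(evaluate_projection_accuracy(curve, marks[0, ], 1),
               class = "arterymap_argument_error")
})
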