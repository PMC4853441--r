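#' Classify lesion laterality per subject
#'
#' Template-space rule: a lesion confined to the infratentorial compartment
#' (when one is available) is "infratentorial"; otherwise a lesion whose
#' voxels all lie strictly on one side of the midline (outside a configurable
#' midline band, default width 0) is "left" or "right"; anything spanning
#' sides or compartments is "multiple".
#'
#' @param cohort A `lesion_cohort`.
#' @param compartments Optional integer 3D array (2 = infratentorial);
#'   defaults to `cohort$compartments` when present.
#' @param midline_band Half-width in mm of a band around x = 0 whose voxels
#'   count as neither side (default 0).
#' @return Tibble with `subject_id`, `laterality` (factor: left, right,
#'   infratentorial, multiple).
#' @export
classify_laterality <- function(cohort, compartments = cohort$compartments,
                                midline_band = 0) {
  wx <- as.numeric(world_x_array(cohort$grid))
  comp <- if (!is.null(compartments)) as.integer(compartments) else NULL
  lat <- vapply(seq_len(n_subjects(cohort)), function(s) {
    idx <- which(cohort$lesions[s, ] == 1L)
    if (length(idx) == 0) return(NA_character_)
    if (!is.null(comp) && all(comp[idx] == 2L)) return("infratentorial")
    if (!is.null(comp) && any(comp[idx] == 2L)) return("multiple")
    x <- wx[idx]
    if (all(x < -midline_band / 2)) return("left")
    if (all(x > midline_band / 2)) return("right")
    "multiple"
  }, character(1))
  tibble(subject_id = cohort$subjects,
         laterality = factor(lat, levels = c("left", "right",
                                             "infratentorial", "multiple")))
}

#' Impairment-by-laterality cross table
#'
#' Counts impaired and unimpaired subjects within each lesion-laterality
#' class, with percentages computed within the impaired (and normal) column
#' groups — e.g. 11 of 18 impaired subjects with a left-hemisphere lesion is
#' reported as 61%. Percentages are `NA` when a group is empty.
#'
#' @param laterality Tibble from [classify_laterality()].
#' @param flags Flags for one test ([dichotomize()] rows).
#' @return Tibble: one row per laterality class with `n_total`,
#'   `impaired_n`, `impaired_pct`, `normal_n`, `normal_pct`.
#' @export
laterality_table <- function(laterality, flags) {
  merged <- laterality |>
    inner_join(flags |> select("subject_id", "impaired"), by = "subject_id") |>
    filter(!is.na(.data$impaired), !is.na(.data$laterality))
  n_imp <- sum(merged$impaired)
  n_nor <- sum(!merged$impaired)
  merged |>
    group_by(.data$laterality, .drop = FALSE) |>
    summarise(n_total = n(), impaired_n = sum(.data$impaired),
              normal_n = sum(!.data$impaired), .groups = "drop") |>
    mutate(impaired_pct = percent_display(.data$impaired_n, n_imp),
           normal_pct = percent_display(.data$normal_n, n_nor)) |>
    select("laterality", "n_total", "impaired_n", "impaired_pct",
           "normal_n", "normal_pct")
}

#' Cohort descriptives
#'
#' Summarizes demographics, raw test scores (mean, sd, range, n),
#' impairment prevalence per dichotomized test, and the
#' impairment-by-laterality tables for the fluency outcomes.
#'
#' @param cohort A `lesion_cohort`.
#' @param flags Output of [dichotomize()] (may cover several tests).
#' @return A `cohort_description`: list of tibbles `demographics`, `tests`,
#'   `impairment`, `laterality` (one table per test in `flags`).
#' @export
describe_cohort <- function(cohort, flags = NULL) {
  b <- cohort$behavior
  demographics <- tibble(
    n = nrow(b),
    age_mean = mean(b$age, na.rm = TRUE), age_sd = stats::sd(b$age, na.rm = TRUE),
    male_n = sum(b$sex == 1, na.rm = TRUE),
    male_pct = percent_display(sum(b$sex == 1, na.rm = TRUE), sum(!is.na(b$sex))),
    education_median = stats::median(b$education, na.rm = TRUE),
    education_min = min(b$education, na.rm = TRUE),
    education_max = max(b$education, na.rm = TRUE)
  )
  score_cols <- setdiff(names(b)[vapply(b, is.numeric, logical(1))],
                        c("age", "sex", "education"))
  tests <- purrr::map(score_cols, function(col) {
    v <- b[[col]]
    tibble(test = col, n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
           sd = stats::sd(v, na.rm = TRUE),
           min = suppressWarnings(min(v, na.rm = TRUE)),
           max = suppressWarnings(max(v, na.rm = TRUE)))
  }) |> bind_rows()

  impairment <- NULL
  laterality_tables <- NULL
  if (!is.null(flags)) {
    impairment <- impairment_summary(flags)
    lat <- classify_laterality(cohort)
    laterality_tables <- flags |>
      group_by(.data$test) |>
      group_map(~ laterality_table(lat, .x)) |>
      stats::setNames(sort(unique(flags$test)))
  }
  structure(list(demographics = demographics, tests = tests,
                 impairment = impairment, laterality = laterality_tables),
            class = "cohort_description")
}

#' @export
print.cohort_description <- function(x, ...) {
  cat("<cohort_description>\n")
  print(x$demographics)
  print(x$tests)
  if (!is.null(x$impairment)) print(x$impairment)
  invisible(x)
}

#' Run the full fluency lesion-mapping study on a cohort
#'
#' Orchestrates every stage end-to-end: fluency scoring, demographic
#' z-adjustment, behavioral correlations, dichotomization, lesion prevalence
#' and test mask, voxel-wise lesion-symptom maps for semantic and phonemic
#' fluency with FDR control, the significance overlap map, dichotomized
#' overlays and subtraction maps, the atlas region report with the
#' significant-voxel region-selection rule, and the hierarchical regressions
#' of adjusted performance on regional infarct volume (with and/or without
#' total-volume adjustment). All parameters and stage-level n accounting are
#' recorded in the run manifest; with the same cohort and parameters the run
#' is fully reproducible.
#'
#' Region selection is per outcome, but the union of selected regions is
#' modeled for both outcomes so every reported region carries both fits.
#'
#' @param cohort A `lesion_cohort` (with an atlas for the ROI stage).
#' @param norms Norm table for dichotomization (`test`, `cutoff`); defaults
#'   to `cohort$norms`. Needs entries for `semantic` and `phonemic`.
#' @param q FDR level (default 0.05).
#' @param min_count Minimum lesion count per tested voxel (default 3).
#' @param min_sig Significant-voxel threshold for region selection
#'   (default 100).
#' @param statistic `"t"` or `"brunner_munzel"`.
#' @param tails `"one"` (default) or `"two"`.
#' @param adjust_total `"both"` (default), `"off"` or `"on"` — whether the
#'   ROI regressions are run without, with, or with both total-infarct-volume
#'   adjustments.
#' @param other_tests Additional behavior columns to z-adjust and correlate
#'   (default: every numeric score column present).
#' @param output_dir Optional directory; when given, all maps (NIfTI), tables
#'   (CSV) and the manifest (JSON) are written there.
#' @return A `fluency_run` list: `scores`, `adjusted`, `correlations`,
#'   `flags`, `prevalence`, `mask`, `stat_maps`, `overlap`, `overlays`,
#'   `subtractions`, `region_report`, `selection`, `roi_volumes`,
#'   `roi_models`, `description`, `manifest`.
#' @export
run_fluency_study <- function(cohort, norms = cohort$norms, q = 0.05,
                              min_count = 3, min_sig = 100,
                              statistic = c("t", "brunner_munzel"),
                              tails = c("one", "two"),
                              adjust_total = c("both", "off", "on"),
                              other_tests = NULL, output_dir = NULL) {
  statistic <- match.arg(statistic)
  tails <- match.arg(tails)
  adjust_total <- match.arg(adjust_total)
  assert_that(!is.null(norms), "no norm table supplied and none attached to the cohort")
  assert_that(q > 0 && q < 1, "q must be in (0, 1)")
  assert_that(min_count >= 1 && min_sig >= 0, "thresholds out of range")

  stage <- "behavior scoring"
  result <- tryCatch({
    scores <- fluency_scores(cohort$behavior) |>
      mutate(semantic = .data$semantic_raw, phonemic = .data$phonemic_raw)
    if (is.null(other_tests)) {
      other_tests <- setdiff(
        names(scores)[vapply(scores, is.numeric, logical(1))],
        c("age", "sex", "education", "animals_2min", "letterN_1min",
          "letterA_1min", "semantic_raw", "phonemic_raw", "semantic", "phonemic"))
    }
    outcome_tests <- c("semantic", "phonemic")

    stage <- "demographic adjustment"
    adjusted <- adjust_for_demographics(scores, c(outcome_tests, other_tests))

    stage <- "correlation table"
    z_wide <- adjusted |>
      select("subject_id", "test", "z") |>
      pivot_wider(names_from = "test", values_from = "z")
    correlations <- correlation_table(z_wide, c(outcome_tests, other_tests))

    stage <- "dichotomization"
    dich_tests <- intersect(c(outcome_tests, other_tests), norms$test)
    flags <- dichotomize(adjusted |> filter(.data$test %in% dich_tests), norms)

    stage <- "lesion prevalence and test mask"
    prevalence <- lesion_prevalence(cohort, display_threshold = min_count)
    mask <- build_test_mask(prevalence, min_count = min_count)

    stage <- "voxel-wise lesion-symptom mapping"
    score_list <- purrr::map(outcome_tests,
                             ~ adjusted |> filter(.data$test == .x)) |>
      stats::setNames(outcome_tests)
    stat_maps <- purrr::map(score_list,
                            ~ vlsm(cohort, .x, mask, statistic = statistic,
                                   q = q, tails = tails))

    stage <- "overlap map"
    overlap <- overlap_map(stat_maps$semantic, stat_maps$phonemic)

    stage <- "lesion subtraction"
    overlays <- purrr::map(outcome_tests,
                           ~ group_overlays(cohort, flags |> filter(.data$test == .x))) |>
      stats::setNames(outcome_tests)
    subtractions <- purrr::map(overlays, subtraction_map)

    stage <- "region report and selection"
    region_report <- NULL; selection <- NULL; roi_volumes <- NULL; roi_models <- NULL
    if (!is.null(cohort$atlas)) {
      region_report <- region_voxel_report(cohort, mask, stat_maps,
                                           scores = score_list)
      selection <- select_regions(region_report, min_sig = min_sig)

      stage <- "roi regressions"
      sel_regions <- unique(selection$region)
      if (length(sel_regions) > 0) {
        roi_volumes <- regional_lesion_volumes(cohort, regions = sel_regions)
        frame <- roi_volumes |>
          select("subject_id", "region", "volume_ml") |>
          pivot_wider(names_from = "region", values_from = "volume_ml") |>
          left_join(lesion_volumes(cohort) |> select("subject_id", "total_lesion_ml"),
                    by = "subject_id") |>
          left_join(z_wide, by = "subject_id") |>
          left_join(cohort$behavior |> select("subject_id", "age", "sex", "education"),
                    by = "subject_id")
        fit_tables <- list()
        if (adjust_total %in% c("off", "both")) {
          fit_tables$unadjusted <- roi_model_table(frame, outcome_tests, sel_regions)
        }
        if (adjust_total %in% c("on", "both")) {
          fit_tables$total_adjusted <- roi_model_table(frame, outcome_tests,
                                                       sel_regions,
                                                       total_volume = "total_lesion_ml")
        }
        roi_models <- bind_rows(fit_tables)
      }
    }

    stage <- "descriptives"
    description <- describe_cohort(cohort, flags)

    manifest <- list(
      package_version = as.character(utils::packageVersion("fluencymap")),
      n_subjects = n_subjects(cohort),
      parameters = list(q = q, min_count = min_count, min_sig = min_sig,
                        statistic_kind = statistic, tails = tails,
                        adjust_total = adjust_total),
      outcomes = outcome_tests, other_tests = other_tests,
      dichotomized_tests = dich_tests,
      n_per_test = stats::setNames(
        as.list(vapply(c(outcome_tests, other_tests),
                       function(t) sum(!is.na(adjusted$z[adjusted$test == t])),
                       numeric(1))),
        c(outcome_tests, other_tests)),
      n_tested_voxels = sum(mask$tested),
      fdr_cutoffs = purrr::map(stat_maps, "fdr_cutoff"),
      n_significant_voxels = purrr::map(stat_maps, ~ sum(.x$significant)),
      selected_regions = if (!is.null(selection)) unique(selection$region) else character(0),
      grid = list(dims = cohort$grid$dims, voxel_size = cohort$grid$voxel_size,
                  space_label = cohort$grid$space_label)
    )

    structure(
      list(scores = scores, adjusted = adjusted, correlations = correlations,
           flags = flags, prevalence = prevalence, mask = mask,
           stat_maps = stat_maps, overlap = overlap, overlays = overlays,
           subtractions = subtractions, region_report = region_report,
           selection = selection, roi_volumes = roi_volumes,
           roi_models = roi_models, description = description,
           manifest = manifest),
      class = "fluency_run"
    )
  }, fluencymap_error = function(e) {
    stop_fm("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  if (!is.null(output_dir)) write_fluency_run(result, cohort, output_dir)
  result
}

#' @export
print.fluency_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<fluency_run> %d subjects | %s statistic, %s-tailed, q = %g, min lesion count %d\n",
              m$n_subjects, m$parameters$statistic_kind, m$parameters$tails,
              m$parameters$q, m$parameters$min_count))
  cat(sprintf("  tested voxels: %d; significant: semantic %d, phonemic %d\n",
              m$n_tested_voxels, m$n_significant_voxels$semantic,
              m$n_significant_voxels$phonemic))
  cat(sprintf("  selected regions (>= %d significant voxels): %s\n",
              m$parameters$min_sig,
              if (length(m$selected_regions)) paste(m$selected_regions, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Write every output of a study run to a directory
#'
#' NIfTI volumes for the prevalence, statistic/p/significance, overlap,
#' overlay and subtraction maps; CSV tables for scores, correlations, flags,
#' region report, selection, volumes, regressions and descriptives; a JSON
#' manifest with every parameter. An `INCOMPLETE` marker is kept in the
#' directory until writing finishes.
#'
#' @param run A `fluency_run`.
#' @param cohort The cohort it was computed from.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fluency_run <- function(run, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(dir, "INCOMPLETE")
  file.create(marker)
  grid <- cohort$grid
  write_volume(run$prevalence$counts, grid, file.path(dir, "prevalence.nii.gz"))
  write_volume(run$mask$tested * 1L, grid, file.path(dir, "test_mask.nii.gz"))
  for (oc in names(run$stat_maps)) {
    write_stat_map(run$stat_maps[[oc]], file.path(dir, paste0("vlsm_", oc)))
    write_subtraction(run$overlays[[oc]], run$subtractions[[oc]],
                      prefix = file.path(dir, paste0("subtraction_", oc)))
  }
  write_volume(run$overlap$category, grid, file.path(dir, "overlap.nii.gz"))

  wcsv <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wcsv(run$adjusted, "adjusted_scores.csv")
  wcsv(run$correlations, "correlations.csv")
  wcsv(run$flags, "impairment_flags.csv")
  wcsv(run$region_report, "region_report.csv")
  wcsv(run$selection, "selected_regions.csv")
  wcsv(run$roi_volumes, "regional_volumes.csv")
  wcsv(run$roi_models, "roi_regressions.csv")
  wcsv(run$description$demographics, "descriptives_demographics.csv")
  wcsv(run$description$tests, "descriptives_tests.csv")
  wcsv(run$description$impairment, "descriptives_impairment.csv")
  if (!is.null(run$description$laterality)) {
    for (t in names(run$description$laterality)) {
      wcsv(run$description$laterality[[t]], paste0("laterality_", t, ".csv"))
    }
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.remove(marker)
  invisible(dir)
}
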