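#' Lesion overlays split by impairment status
#'
#' Builds two lesion-prevalence maps — one for subjects flagged impaired on a
#' test, one for subjects with normal performance — the ingredients of a
#' lesion subtraction analysis. Subjects with an undefined flag are excluded
#' and counted.
#'
#' @param cohort A `lesion_cohort`.
#' @param flags Data frame with `subject_id` and `impaired` (logical);
#'   typically one test's rows from [dichotomize()].
#' @return A `group_overlay`: `grid`, `impaired_counts` and `normal_counts`
#'   (integer 3D arrays), `n_impaired`, `n_normal`, `n_missing_flag`, `test`.
#' @export
group_overlays <- function(cohort, flags) {
  flags <- as_tibble(flags)
  assert_that(all(c("subject_id", "impaired") %in% names(flags)),
              "flags must have subject_id and impaired")
  if ("test" %in% names(flags)) {
    assert_that(length(unique(flags$test)) == 1,
                "flags contain multiple tests; filter to one first")
  }
  imp <- flags$impaired[match(cohort$subjects, flags$subject_id)]
  n_missing <- sum(is.na(imp))
  imp_ids <- which(!is.na(imp) & imp)
  nor_ids <- which(!is.na(imp) & !imp)
  if (length(imp_ids) == 0) stop_fm("impaired group is empty; cannot form overlays")
  if (length(nor_ids) == 0) stop_fm("normal group is empty; cannot form overlays")
  dims <- cohort$grid$dims
  structure(
    list(grid = cohort$grid,
         impaired_counts = array(as.integer(colSums(cohort$lesions[imp_ids, , drop = FALSE])), dims),
         normal_counts = array(as.integer(colSums(cohort$lesions[nor_ids, , drop = FALSE])), dims),
         n_impaired = length(imp_ids), n_normal = length(nor_ids),
         n_missing_flag = n_missing,
         test = if ("test" %in% names(flags)) unique(flags$test) else NA_character_),
    class = "group_overlay"
  )
}

#' @export
print.group_overlay <- function(x, ...) {
  cat(sprintf("<group_overlay> %s: %d impaired vs %d normal (%d without flag)\n",
              x$test, x$n_impaired, x$n_normal, x$n_missing_flag))
  invisible(x)
}

#' Lesion subtraction map
#'
#' Per voxel, the difference in lesion prevalence (percentage points) between
#' the impaired and the unimpaired group:
#' `100 * impaired_count / n_impaired - 100 * normal_count / n_normal`.
#' Values lie in \[-100, 100\]; positive values mark voxels more frequently
#' lesioned in impaired subjects. No statistical thresholding is applied —
#' the subtraction map is a qualitative robustness check of the voxel-wise
#' results. For display the map is rounded half-up to integer percent (e.g.
#' 3/18 vs 0/75 gives 16.67, shown as 17); the exact values are retained.
#'
#' @param overlay A `group_overlay` from [group_overlays()].
#' @return A `subtraction_map`: `grid`, `percent_difference` (exact, 3D),
#'   `display` (integer percent, 3D), group sizes, `test`.
#' @export
subtraction_map <- function(overlay) {
  pct <- 100 * overlay$impaired_counts / overlay$n_impaired -
    100 * overlay$normal_counts / overlay$n_normal
  structure(
    list(grid = overlay$grid, percent_difference = pct,
         display = round_half_up(pct),
         n_impaired = overlay$n_impaired, n_normal = overlay$n_normal,
         test = overlay$test),
    class = "subtraction_map"
  )
}

#' @export
print.subtraction_map <- function(x, ...) {
  cat(sprintf("<subtraction_map> %s: range %+.1f to %+.1f points (%d impaired vs %d normal)\n",
              x$test, min(x$percent_difference), max(x$percent_difference),
              x$n_impaired, x$n_normal))
  invisible(x)
}

#' @rdname tidy.count_map
#' @export
tidy.subtraction_map <- function(x, ...) {
  voxel_tibble(x$grid,
               list(percent_difference = x$percent_difference, display = x$display),
               keep = x$percent_difference != 0)
}

#' Write overlay and subtraction volumes plus a JSON sidecar
#'
#' @param overlay A `group_overlay`.
#' @param subtraction Matching `subtraction_map` (computed if `NULL`).
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_subtraction <- function(overlay, subtraction = NULL, prefix) {
  subtraction <- subtraction %||% subtraction_map(overlay)
  write_volume(overlay$impaired_counts, overlay$grid,
               paste0(prefix, "_overlay_impaired.nii.gz"))
  write_volume(overlay$normal_counts, overlay$grid,
               paste0(prefix, "_overlay_normal.nii.gz"))
  write_volume(subtraction$percent_difference, overlay$grid,
               paste0(prefix, "_subtraction.nii.gz"))
  jsonlite::write_json(
    list(test = overlay$test, n_impaired = overlay$n_impaired,
         n_normal = overlay$n_normal, n_missing_flag = overlay$n_missing_flag),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
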