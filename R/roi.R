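#' Per-region voxel report over the VLSM results
#'
#' Projects the atlas regions onto the voxel-wise results and tallies, for
#' every region and outcome: region size, tested voxels, significant voxels
#' and their percentage of tested voxels, the number of patients with at
#' least one lesioned voxel in the region, and (when scores are supplied) the
#' same patient count restricted to subjects who entered that outcome's
#' analysis.
#'
#' @param cohort A `lesion_cohort`.
#' @param mask A `test_mask`.
#' @param stat_maps Named list of `stat_map` objects, one per outcome.
#' @param atlas An `atlas_volume`; defaults to `cohort$atlas`.
#' @param scores Optional named list (same names as `stat_maps`) of data
#'   frames with `subject_id` and `z`, used for the per-analysis patient
#'   counts; `NA` otherwise.
#' @return A tibble, one row per region x outcome: `label`, `region`,
#'   `patients_with_lesion`, `patients_with_lesion_analyzed`,
#'   `region_size_voxels`, `tested_voxels`, `outcome`, `significant_voxels`,
#'   `percent_of_tested` (exact; 0 when no voxel tested).
#' @export
region_voxel_report <- function(cohort, mask, stat_maps, atlas = cohort$atlas,
                                scores = NULL) {
  assert_that(!is.null(atlas), "no atlas available")
  check_same_grid(cohort$grid, atlas$grid, "atlas")
  check_same_grid(cohort$grid, mask$grid, "test mask")
  assert_that(length(stat_maps) > 0 && !is.null(names(stat_maps)),
              "stat_maps must be a named list")
  for (sm in stat_maps) check_same_grid(cohort$grid, sm$grid, "stat map")

  labels <- atlas$region_table$label
  lab_vec <- as.integer(atlas$labels)
  purrr::map(seq_along(labels), function(r) {
    lab <- labels[r]
    in_region <- lab_vec == lab
    idx <- which(in_region)
    region_size <- length(idx)
    tested <- sum(mask$tested[idx])
    les_in_region <- cohort$lesions[, idx, drop = FALSE]
    has_lesion <- rowSums(les_in_region) >= 1
    purrr::map(names(stat_maps), function(oc) {
      sig <- sum(stat_maps[[oc]]$significant[idx])
      analyzed <- NA_integer_
      if (!is.null(scores) && oc %in% names(scores)) {
        sc <- scores[[oc]]
        zc <- sc$z[match(cohort$subjects, sc$subject_id)]
        analyzed <- sum(has_lesion & !is.na(zc))
      }
      tibble(label = lab, region = atlas$region_table$region[r],
             patients_with_lesion = sum(has_lesion),
             patients_with_lesion_analyzed = analyzed,
             region_size_voxels = region_size, tested_voxels = tested,
             outcome = oc, significant_voxels = sig,
             percent_of_tested = if (tested > 0) 100 * sig / tested else 0)
    }) |> bind_rows()
  }) |> bind_rows()
}

#' Select regions of interest from a voxel report
#'
#' A region is selected for an outcome when it contains at least `min_sig`
#' voxels with a significant lesion-behavior association.
#'
#' @param report Output of [region_voxel_report()].
#' @param min_sig Minimum significant voxels (default 100).
#' @return Tibble of selected rows (`outcome`, `label`, `region`,
#'   `significant_voxels`), with `min_sig` recorded as an attribute.
#' @export
select_regions <- function(report, min_sig = 100) {
  out <- report |>
    filter(.data$significant_voxels >= min_sig) |>
    select("outcome", "label", "region", "significant_voxels") |>
    arrange(.data$outcome, desc(.data$significant_voxels))
  attr(out, "min_sig") <- min_sig
  out
}

#' Lesion volume of one subject within one atlas region
#'
#' @param map A `lesion_map`.
#' @param atlas An `atlas_volume` on the same grid.
#' @param region Region name or integer label.
#' @return One-row tibble: `subject_id`, `region`, `label`, `volume_ml`,
#'   `total_lesion_ml` (1000 mm^3 = 1 ml).
#' @export
regional_lesion_volume <- function(map, atlas, region) {
  check_same_grid(map$grid, atlas$grid, "atlas")
  rt <- atlas$region_table
  row <- if (is.numeric(region)) which(rt$label == region) else which(rt$region == region)
  assert_that(length(row) == 1, "unknown atlas region '%s'", as.character(region))
  vv <- voxel_volume_ml(map$grid)
  tibble(subject_id = map$subject_id, region = rt$region[row], label = rt$label[row],
         volume_ml = sum(map$voxels[atlas$labels == rt$label[row]]) * vv,
         total_lesion_ml = sum(map$voxels) * vv)
}

#' Regional lesion volumes for all subjects of a cohort
#'
#' @param cohort A `lesion_cohort`.
#' @param atlas An `atlas_volume`; defaults to `cohort$atlas`.
#' @param regions Region names or labels to include (default: all).
#' @return Tidy tibble: `subject_id`, `region`, `label`, `volume_ml`,
#'   `total_lesion_ml`.
#' @export
regional_lesion_volumes <- function(cohort, atlas = cohort$atlas, regions = NULL) {
  assert_that(!is.null(atlas), "no atlas available")
  check_same_grid(cohort$grid, atlas$grid, "atlas")
  rt <- atlas$region_table
  if (!is.null(regions)) {
    rows <- if (is.numeric(regions)) match(regions, rt$label) else match(regions, rt$region)
    assert_that(!anyNA(rows), "unknown atlas region(s): %s",
                paste(regions[is.na(rows)], collapse = ", "))
    rt <- rt[rows, ]
  }
  vv <- voxel_volume_ml(cohort$grid)
  lab_vec <- as.integer(atlas$labels)
  indicator <- vapply(rt$label, function(l) as.numeric(lab_vec == l),
                      numeric(length(lab_vec)))
  counts <- cohort$lesions %*% indicator          # subjects x regions
  total <- rowSums(cohort$lesions) * vv
  tibble(subject_id = rep(cohort$subjects, times = nrow(rt)),
         region = rep(rt$region, each = n_subjects(cohort)),
         label = rep(rt$label, each = n_subjects(cohort)),
         volume_ml = as.numeric(counts) * vv,
         total_lesion_ml = rep(total, times = nrow(rt)))
}

#' Hierarchical regression of adjusted performance on regional lesion volume
#'
#' Fits a base linear model of the demographically adjusted z score on age,
#' sex and education (optionally plus total infarct volume), then adds the
#' regional infarct volume (ml). Reports R-squared of both models, the
#' partial F-test p value for the increase in explained variance (for a
#' single added regressor this equals the coefficient's two-sided t-test),
#' and the unstandardized coefficient B — the change in z score per 1 ml of
#' regional infarct volume — with its 95% t-based confidence interval.
#' Listwise deletion within the fit; the n used is recorded.
#'
#' @param data Data frame with the outcome, covariates and volume columns.
#' @param outcome Name of the z-score outcome column.
#' @param roi_volume Name of the regional volume column (ml).
#' @param covariates Demographic covariate columns
#'   (default `c("age", "sex", "education")`).
#' @param total_volume Optional name of the total-infarct-volume column; when
#'   given it enters the *base* model, so B is adjusted for total volume.
#' @param min_n Minimum complete cases (default 10).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return A `roi_model_fit` (supports [generics::tidy()] and
#'   [generics::glance()]).
#' @export
fit_roi_model <- function(data, outcome, roi_volume,
                          covariates = c("age", "sex", "education"),
                          total_volume = NULL, min_n = 10, conf_level = 0.95) {
  data <- as_tibble(data)
  cols <- c(outcome, covariates, roi_volume, total_volume)
  miss <- setdiff(cols, names(data))
  assert_that(length(miss) == 0, "missing columns: %s", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(data[, cols])
  d <- data[cc, cols]
  assert_that(nrow(d) >= min_n, "only %d complete cases (need >= %d)", nrow(d), min_n)

  base_terms <- c(covariates, total_volume)
  f_base <- stats::reformulate(sprintf("`%s`", base_terms), response = sprintf("`%s`", outcome))
  f_full <- stats::reformulate(sprintf("`%s`", c(base_terms, roi_volume)),
                               response = sprintf("`%s`", outcome))
  fit_base <- stats::lm(f_base, data = d)
  if (stats::sd(d[[roi_volume]]) == 0) {
    # degenerate but well-defined: a constant regional volume cannot explain
    # variance, so the full model collapses onto the base model
    return(structure(
      list(outcome = outcome, roi_volume = roi_volume,
           adjusted_for_total_volume = !is.null(total_volume),
           n = nrow(d),
           r2_base = summary(fit_base)$r.squared,
           r2_full = summary(fit_base)$r.squared,
           p_delta = 1, f_delta = 0,
           B = NA_real_, ci95 = c(NA_real_, NA_real_), conf_level = conf_level,
           fit_base = fit_base, fit_full = fit_base,
           note = "regional volume constant over complete cases"),
      class = "roi_model_fit"
    ))
  }
  fit_full <- stats::lm(f_full, data = d)
  if (anyNA(stats::coef(fit_full))) {
    bad <- names(stats::coef(fit_full))[is.na(stats::coef(fit_full))]
    stop_fm("rank-deficient design: coefficient(s) not estimable: %s (is '%s' collinear with the other predictors?)",
            paste(bad, collapse = ", "), roi_volume)
  }
  cmp <- stats::anova(fit_base, fit_full)
  coef_name <- sprintf("`%s`", roi_volume)
  if (!coef_name %in% names(stats::coef(fit_full))) coef_name <- roi_volume
  B <- unname(stats::coef(fit_full)[coef_name])
  ci <- unname(stats::confint(fit_full, coef_name, level = conf_level))

  structure(
    list(outcome = outcome, roi_volume = roi_volume,
         adjusted_for_total_volume = !is.null(total_volume),
         n = nrow(d),
         r2_base = summary(fit_base)$r.squared,
         r2_full = summary(fit_full)$r.squared,
         p_delta = cmp$`Pr(>F)`[2], f_delta = cmp$F[2],
         B = B, ci95 = as.numeric(ci), conf_level = conf_level,
         fit_base = fit_base, fit_full = fit_full),
    class = "roi_model_fit"
  )
}

#' @export
print.roi_model_fit <- function(x, ...) {
  cat(sprintf("<roi_model_fit> %s ~ demographics%s + %s (n = %d)\n",
              x$outcome, if (x$adjusted_for_total_volume) " + total volume" else "",
              x$roi_volume, x$n))
  cat(sprintf("  R2 %.3f -> %.3f, p(dR2) = %.4g; B = %.3f per ml (%d%% CI %.3f to %.3f)\n",
              x$r2_base, x$r2_full, x$p_delta, x$B,
              round(100 * x$conf_level), x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Tidy a ROI regression fit
#'
#' @param x A `roi_model_fit`.
#' @param ... Unused.
#' @return Coefficient-level tibble of the full model (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.roi_model_fit <- function(x, ...) {
  s <- summary(x$fit_full)$coefficients
  tibble(term = gsub("`", "", rownames(s)), estimate = s[, 1],
         std.error = s[, 2], statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a ROI regression fit
#'
#' @param x A `roi_model_fit`.
#' @param ... Unused.
#' @return Tibble with `outcome`, `region_volume`, `n`, `r2_base`, `r2_full`,
#'   `delta_r2`, `p_delta`, `B`, `ci_low`, `ci_high`,
#'   `adjusted_for_total_volume`.
#' @export
glance.roi_model_fit <- function(x, ...) {
  tibble(outcome = x$outcome, region_volume = x$roi_volume, n = x$n,
         r2_base = x$r2_base, r2_full = x$r2_full,
         delta_r2 = x$r2_full - x$r2_base, p_delta = x$p_delta,
         B = x$B, ci_low = x$ci95[1], ci_high = x$ci95[2],
         adjusted_for_total_volume = x$adjusted_for_total_volume)
}

#' Regression table across regions and outcomes
#'
#' Fits [fit_roi_model()] for every combination of outcome and region volume
#' column and stacks the one-row summaries — the package's analogue of a
#' results table of hierarchical regressions per region of interest.
#'
#' @param data Modeling frame: one row per subject with z-score outcome
#'   columns, `age`/`sex`/`education`, one volume column per region (ml), and
#'   optionally a total-volume column.
#' @param outcomes Character vector of outcome column names.
#' @param region_cols Character vector of regional volume column names.
#' @param total_volume Optional total-volume column (passed through).
#' @param ... Further arguments to [fit_roi_model()].
#' @return Tibble of stacked [glance.roi_model_fit()] rows.
#' @export
roi_model_table <- function(data, outcomes, region_cols, total_volume = NULL, ...) {
  tidyr::expand_grid(outcome = outcomes, region = region_cols) |>
    purrr::pmap(function(outcome, region) {
      glance(fit_roi_model(data, outcome = outcome, roi_volume = region,
                           total_volume = total_volume, ...))
    }) |>
    bind_rows()
}
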