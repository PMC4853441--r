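#' Assemble a lesion cohort
#'
#' Matches per-subject binary lesion maps with a behavior table by
#' `subject_id`. Subjects present on only one side are excluded and listed in
#' the result; per-test missingness is kept as explicit `NA` and handled
#' pairwise by downstream analyses. All maps must share one grid exactly.
#'
#' @param lesion_maps List of `lesion_map` objects (one per subject).
#' @param behavior Behavior data frame with columns `subject_id`, `age`,
#'   `sex`, `education`, plus test-score columns.
#' @param atlas Optional `atlas_volume` on the same grid.
#' @param tol Affine tolerance (mm) for grid checks.
#' @return A `lesion_cohort`: grid, subject ids, an internal subjects-by-voxels
#'   lesion matrix, the behavior tibble (aligned), the atlas, and a tibble of
#'   `excluded` subjects with reasons.
#' @export
assemble_cohort <- function(lesion_maps, behavior, atlas = NULL, tol = 1e-4) {
  assert_that(length(lesion_maps) >= 1, "need at least one lesion map")
  behavior <- validate_behavior(behavior)
  grid <- lesion_maps[[1]]$grid
  map_ids <- map_chr(lesion_maps, "subject_id")
  assert_that(!anyDuplicated(map_ids), "duplicate subject_id among lesion maps")
  for (m in lesion_maps) check_same_grid(grid, m$grid, m$subject_id, tol = tol)

  matched <- intersect(map_ids, behavior$subject_id)
  assert_that(length(matched) >= 2, "fewer than 2 subjects match between lesion maps and behavior")
  excluded <- bind_rows(
    tibble(subject_id = setdiff(map_ids, matched), reason = "no behavior record"),
    tibble(subject_id = setdiff(behavior$subject_id, matched), reason = "no lesion map")
  )

  lesions <- do.call(rbind, lapply(lesion_maps[match(matched, map_ids)],
                                   function(m) as.integer(m$voxels)))
  rownames(lesions) <- matched
  behavior <- behavior[match(matched, behavior$subject_id), ]
  if (!is.null(atlas)) check_same_grid(grid, atlas$grid, "atlas", tol = tol)

  new_cohort(grid, matched, lesions, behavior, atlas = atlas, excluded = excluded)
}

new_cohort <- function(grid, subjects, lesions, behavior, atlas = NULL,
                       truth = NULL, excluded = tibble(subject_id = character(),
                                                       reason = character())) {
  structure(
    list(grid = grid, subjects = subjects, lesions = lesions,
         behavior = behavior, atlas = atlas, truth = truth, excluded = excluded),
    class = "lesion_cohort"
  )
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat(sprintf("<lesion_cohort> %d subjects on a %s grid (%s)\n",
              n_subjects(x), paste(x$grid$dims, collapse = "x"),
              x$grid$space_label))
  if (nrow(x$excluded)) cat(sprintf("  %d excluded at assembly\n", nrow(x$excluded)))
  if (!is.null(x$atlas)) cat(sprintf("  atlas: %d regions\n", nrow(x$atlas$region_table)))
  if (!is.null(x$truth)) cat("  synthetic ground truth attached\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A `lesion_cohort`.
#' @return Integer count.
#' @export
n_subjects <- function(cohort) length(cohort$subjects)

#' Extract one subject's lesion map from a cohort
#' @param cohort A `lesion_cohort`.
#' @param subject_id Subject identifier.
#' @return A `lesion_map`.
#' @export
cohort_lesion_map <- function(cohort, subject_id) {
  assert_that(subject_id %in% cohort$subjects, "unknown subject '%s'", subject_id)
  lesion_map(subject_id, cohort$grid,
             array(cohort$lesions[subject_id, ], dim = cohort$grid$dims))
}

#' Per-subject total lesion volumes
#' @param cohort A `lesion_cohort`.
#' @return Tibble with `subject_id`, `n_voxels`, `total_lesion_ml`.
#' @export
lesion_volumes <- function(cohort) {
  nv <- rowSums(cohort$lesions)
  tibble(subject_id = cohort$subjects, n_voxels = as.integer(nv),
         total_lesion_ml = nv * voxel_volume_ml(cohort$grid))
}

#' Voxel-wise lesion prevalence map
#'
#' Sums the binary lesion maps across subjects, giving the number of patients
#' with a lesion at each voxel. A display threshold (default 3, matching the
#' minimum lesion count used for the voxel-wise analyses) marks the voxels
#' shown in prevalence figures.
#'
#' @param cohort A `lesion_cohort`.
#' @param display_threshold Minimum count for display flagging.
#' @return A `count_map`: `grid`, `counts` (integer 3D array),
#'   `n_subjects`, `display_threshold`.
#' @export
lesion_prevalence <- function(cohort, display_threshold = 3) {
  counts <- colSums(cohort$lesions)
  structure(
    list(grid = cohort$grid,
         counts = array(as.integer(counts), dim = cohort$grid$dims),
         n_subjects = n_subjects(cohort),
         display_threshold = display_threshold),
    class = "count_map"
  )
}

#' @export
print.count_map <- function(x, ...) {
  cat(sprintf("<count_map> max count %d / %d subjects; %d voxels at count >= %d\n",
              max(x$counts), x$n_subjects, sum(x$counts >= x$display_threshold),
              x$display_threshold))
  invisible(x)
}

#' Turn a voxel volume object into a tidy tibble
#'
#' One row per voxel (optionally only nonzero / tested voxels), with 0-based
#' voxel indices, world-mm coordinates and the voxel value(s).
#'
#' @param x A `count_map`.
#' @param all_voxels Keep zero-count voxels too? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble with `i`, `j`, `k`, `x`, `y`, `z`, `count`.
#' @export
tidy.count_map <- function(x, all_voxels = FALSE, ...) {
  voxel_tibble(x$grid, list(count = x$counts),
               keep = if (all_voxels) NULL else x$counts > 0)
}

# shared helper: values = named list of 3D arrays; keep = logical array or NULL
voxel_tibble <- function(grid, values, keep = NULL) {
  if (is.null(keep)) keep <- array(TRUE, dim = grid$dims)
  idx <- which(keep)
  ijk <- arrayInd(idx, grid$dims) - 1L
  world <- t(grid$affine[1:3, 1:3] %*% t(ijk) + grid$affine[1:3, 4])
  out <- tibble(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                x = world[, 1], y = world[, 2], z = world[, 3])
  for (nm in names(values)) out[[nm]] <- values[[nm]][idx]
  out
}

#' Write a cohort to disk as NIfTI maps + CSV behavior + JSON manifest
#'
#' @param cohort A `lesion_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "lesions"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in cohort$subjects) {
    p <- file.path(dir, "lesions", paste0(id, ".nii.gz"))
    write_lesion_map(cohort_lesion_map(cohort, id), p)
    paths[id] <- p
  }
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"), row.names = FALSE)
  if (!is.null(cohort$atlas)) {
    write_volume(cohort$atlas$labels, cohort$grid, file.path(dir, "atlas.nii.gz"))
    utils::write.csv(cohort$atlas$region_table, file.path(dir, "atlas_regions.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$truth)) {
    # ground truth is segregated from analysis inputs: separate file, never
    # read by any analysis stage
    jsonlite::write_json(truth_manifest(cohort$truth),
                         file.path(dir, "synthetic_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    n_subjects = n_subjects(cohort),
    subjects = cohort$subjects,
    lesion_files = file.path("lesions", paste0(cohort$subjects, ".nii.gz")),
    grid = list(dims = cohort$grid$dims, voxel_size = cohort$grid$voxel_size,
                space_label = cohort$grid$space_label)
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

truth_manifest <- function(truth) {
  list(outcomes = names(truth$weights_ml),
       causal_regions = truth$causal_regions,
       weights_raw_per_ml = truth$weights_ml,
       demographic_effects = truth$demographics,
       noise_sd = truth$noise_sd,
       baselines = truth$baselines)
}
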