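grid_from_nifti <- function(img, space_label = "file") {
  d <- dim(img)
  if (length(d) == 4 && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3) stop_fm("expected a 3D volume, got %d dimensions", length(d))
  grid_geometry(dims = d,
                voxel_size = RNifti::pixdim(img)[1:3],
                affine = unclass(RNifti::xform(img))[, , drop = FALSE],
                space_label = space_label)
}

#' Read a binary lesion map from a NIfTI file
#'
#' Reads a 3D NIfTI-1 volume, binarizes it (any strictly positive voxel value
#' becomes 1 — manual segmentations are nominally binary but interpolation
#' during registration can leave fractional values), and verifies the grid
#' against the expected cohort grid.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param expected_grid Optional `grid_geometry` the volume must match.
#' @param subject_id Subject identifier; defaults to the file name stem.
#' @param tol Affine comparison tolerance in mm (absolute, per element).
#' @return A `lesion_map`: list with `subject_id`, `grid`, and `voxels`
#'   (integer 3D array in \{0, 1\}).
#' @export
read_lesion_map <- function(path, expected_grid = NULL, subject_id = NULL,
                            tol = 1e-4) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, space_label = expected_grid$space_label %||% "file")
  if (!is.null(expected_grid)) check_same_grid(expected_grid, grid, path, tol = tol)
  subject_id <- subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_map(subject_id, grid, array(as.numeric(img), dim = grid$dims))
}

#' Construct a lesion map from an array
#'
#' @param subject_id Subject identifier.
#' @param grid A `grid_geometry`.
#' @param voxels 3D numeric array; strictly positive values are coerced to 1.
#' @return A `lesion_map`.
#' @export
lesion_map <- function(subject_id, grid, voxels) {
  assert_that(identical(dim(voxels), as.integer(grid$dims)),
              "voxel array dims do not match grid for subject %s", subject_id)
  structure(
    list(subject_id = as.character(subject_id), grid = grid,
         voxels = array(as.integer(voxels > 0), dim = grid$dims)),
    class = "lesion_map"
  )
}

#' @export
print.lesion_map <- function(x, ...) {
  cat(sprintf("<lesion_map> subject %s: %d lesioned voxels (%.2f ml)\n",
              x$subject_id, sum(x$voxels), sum(x$voxels) * voxel_volume_ml(x$grid)))
  invisible(x)
}

write_volume <- function(voxels, grid, path) {
  img <- RNifti::asNifti(voxels)
  RNifti::pixdim(img) <- grid$voxel_size
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(grid$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a lesion map (or any volume) to NIfTI
#'
#' @param x A `lesion_map`, or a plain 3D array (then `grid` is required).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param grid Grid for plain arrays.
#' @return The path, invisibly.
#' @export
write_lesion_map <- function(x, path, grid = NULL) {
  if (inherits(x, "lesion_map")) write_volume(x$voxels, x$grid, path)
  else write_volume(x, grid, path)
}

#' Read an integer-labeled atlas volume
#'
#' @param path NIfTI file of integer region labels (0 = unlabeled).
#' @param region_table Data frame with columns `label` (integer) and `region`
#'   (name). Every nonzero label present in the volume must appear here.
#' @param expected_grid Optional grid to verify against.
#' @param tol Affine tolerance (mm).
#' @return An `atlas_volume`: list with `grid`, `labels` (integer 3D array)
#'   and `region_table` (tibble).
#' @export
read_atlas_volume <- function(path, region_table, expected_grid = NULL, tol = 1e-4) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img, space_label = expected_grid$space_label %||% "file")
  if (!is.null(expected_grid)) check_same_grid(expected_grid, grid, path, tol = tol)
  atlas_volume(grid, array(as.integer(round(img)), dim = grid$dims), region_table)
}

#' Construct an atlas volume
#'
#' @param grid A `grid_geometry`.
#' @param labels Integer 3D array of region labels (0 = unlabeled).
#' @param region_table Data frame with columns `label`, `region`.
#' @return An `atlas_volume`.
#' @export
atlas_volume <- function(grid, labels, region_table) {
  region_table <- as_tibble(region_table)
  assert_that(all(c("label", "region") %in% names(region_table)),
              "region_table needs columns 'label' and 'region'")
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, region_table$label)
  assert_that(length(missing) == 0,
              "atlas labels missing from region_table: %s",
              paste(missing, collapse = ", "))
  structure(list(grid = grid, labels = array(as.integer(labels), dim = grid$dims),
                 region_table = region_table),
            class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf("<atlas_volume> %d regions, %d labeled voxels\n",
              nrow(x$region_table), sum(x$labels != 0L)))
  invisible(x)
}

#' Read a behavior table from delimited text
#'
#' Expects a header with at least `subject_id`, `age`, `sex`, `education`;
#' any further columns are treated as test scores. Empty cells and "NA" are
#' missing values. `column_map` renames nonstandard headers, e.g.
#' `c(animals_2min = "animals")`.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @param column_map Named character vector `new_name = old_name`.
#' @return A tibble, one row per subject.
#' @export
read_behavior_table <- function(path, column_map = NULL) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(column_map)) {
    for (new in names(column_map)) {
      old <- column_map[[new]]
      assert_that(old %in% names(df), "column '%s' not found in %s", old, path)
      names(df)[names(df) == old] <- new
    }
  }
  validate_behavior(as_tibble(df))
}

validate_behavior <- function(behavior) {
  behavior <- as_tibble(behavior)
  need <- c("subject_id", "age", "sex", "education")
  miss <- setdiff(need, names(behavior))
  assert_that(length(miss) == 0, "behavior table lacks columns: %s",
              paste(miss, collapse = ", "))
  behavior$subject_id <- as.character(behavior$subject_id)
  assert_that(!anyDuplicated(behavior$subject_id),
              "duplicate subject_id in behavior table")
  edu <- behavior$education[!is.na(behavior$education)]
  assert_that(all(edu %in% 1:7), "education must be an ordinal 1-7")
  for (col in intersect(c("animals_2min", "letterN_1min", "letterA_1min"),
                        names(behavior))) {
    v <- behavior[[col]][!is.na(behavior[[col]])]
    assert_that(all(v >= 0 & v == round(v)),
                "fluency counts in '%s' must be non-negative integers", col)
  }
  behavior
}

#' Read a norm table of dichotomization cutoffs
#'
#' @param path CSV or JSON file with fields `test` and `cutoff` (the normative
#'   5th-percentile score below which performance is classified as impaired).
#' @return A tibble with columns `test`, `cutoff`.
#' @export
read_norm_table <- function(path) {
  norms <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as_tibble(jsonlite::fromJSON(path))
  } else {
    as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  assert_that(all(c("test", "cutoff") %in% names(norms)),
              "norm table needs columns 'test' and 'cutoff'")
  assert_that(all(is.finite(norms$cutoff)), "norm cutoffs must be finite")
  norms
}
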