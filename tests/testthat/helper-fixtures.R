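# Small fixtures built in code.

tiny_grid <- function(dims = c(6, 6, 6), voxel = 1) {
  grid_geometry(dims, voxel, space_label = "toy")
}

# lesion map from 1-based linear voxel indices
make_map <- function(id, grid, idx) {
  vox <- array(0L, dim = grid$dims)
  vox[idx] <- 1L
  lesion_map(id, grid, vox)
}

# behavior row builder with sensible defaults
make_behavior <- function(ids, age = 60, sex = 0, education = 5,
                          animals = 20, letterN = 8, letterA = 8, ...) {
  tibble::tibble(subject_id = ids,
                 age = rep_len(age, length(ids)),
                 sex = rep_len(sex, length(ids)),
                 education = rep_len(education, length(ids)),
                 animals_2min = rep_len(animals, length(ids)),
                 letterN_1min = rep_len(letterN, length(ids)),
                 letterA_1min = rep_len(letterA, length(ids)),
                 ...)
}

# deterministic cohort: n subjects, each lesioning a chosen set of voxels
make_cohort <- function(lesion_idx, behavior = NULL, grid = tiny_grid(),
                        atlas = NULL) {
  ids <- sprintf("p%02d", seq_along(lesion_idx))
  maps <- purrr::map2(ids, lesion_idx, ~ make_map(.x, grid, .y))
  behavior <- behavior %||% make_behavior(ids)
  assemble_cohort(maps, behavior, atlas = atlas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
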