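test_that("region reports equal brute-force label-wise tallies", {
  set.seed(61)
  space <- toy_space(c(16, 16, 16))
  cohort <- simulate_fluency_cohort(n = 25, space = space,
                                    volume_range = c(15, 120), seed = 13)
  mask <- build_test_mask(lesion_prevalence(cohort), min_count = 3)
  scores <- tibble::tibble(subject_id = cohort$subjects, z = rnorm(25))
  sm <- vlsm(cohort, scores, mask, outcome = "A")
  report <- region_voxel_report(cohort, mask, list(A = sm),
                                scores = list(A = scores))

  atlas <- cohort$atlas
  for (i in seq_len(nrow(report))) {
    in_region <- atlas$labels == report$label[i]
    expect_equal(report$region_size_voxels[i], sum(in_region))
    expect_equal(report$tested_voxels[i], sum(mask$tested & in_region))
    expect_equal(report$significant_voxels[i], sum(sm$significant & in_region))
    brute_pat <- sum(vapply(cohort$subjects, function(id)
      any(cohort_lesion_map(cohort, id)$voxels[in_region] == 1L), logical(1)))
    expect_equal(report$patients_with_lesion[i], brute_pat)
  }
  # invariant chain: significant <= tested <= region size
  expect_true(all(report$significant_voxels <= report$tested_voxels))
  expect_true(all(report$tested_voxels <= report$region_size_voxels))
  # percent base is the tested count
  nz <- report$tested_voxels > 0
  expect_equal(report$percent_of_tested[nz],
               100 * report$significant_voxels[nz] / report$tested_voxels[nz])

  # an empty significance map zeroes the counts
  sm0 <- sm; sm0$significant[] <- FALSE
  report0 <- region_voxel_report(cohort, mask, list(A = sm0))
  expect_true(all(report0$significant_voxels == 0))
})

test_that("region selection applies the >= 100 significant-voxel rule and is monotone", {
  report <- tibble::tibble(label = 1:3, region = c("r1", "r2", "r3"),
                           patients_with_lesion = 5,
                           patients_with_lesion_analyzed = 5,
                           region_size_voxels = 500, tested_voxels = 400,
                           outcome = "semantic",
                           significant_voxels = c(100, 99, 350),
                           percent_of_tested = 0)
  sel <- select_regions(report, min_sig = 100)
  expect_setequal(sel$region, c("r1", "r3"))   # 100 selected, 99 not

  expect_equal(nrow(select_regions(report[0, ], 100)), 0)

  # larger threshold selects a subset
  sel_strict <- select_regions(report, min_sig = 200)
  expect_true(all(sel_strict$region %in% sel$region))
})

test_that("regional volumes convert voxel counts to ml and add over disjoint regions", {
  grid <- grid_geometry(c(12, 12, 12), voxel_size = 1)
  labels <- array(0L, dim = c(12, 12, 12))
  labels[1:1000] <- 1L
  labels[1001:1200] <- 2L
  atlas <- atlas_volume(grid, labels, tibble::tibble(label = 1:2,
                                                     region = c("A", "B")))
  # 1000 lesioned 1 mm^3 voxels inside region A -> exactly 1 ml
  m <- make_map("s1", grid, 1:1000)
  rv <- regional_lesion_volume(m, atlas, "A")
  expect_equal(rv$volume_ml, 1.0)
  expect_equal(regional_lesion_volume(m, atlas, "B")$volume_ml, 0)
  expect_error(regional_lesion_volume(m, atlas, "nope"), "unknown")

  # random map: per-region volumes match brute force and sum to <= total
  set.seed(62)
  m2 <- make_map("s2", grid, sample(1728, 400))
  for (reg in c("A", "B")) {
    lab <- if (reg == "A") 1L else 2L
    expect_equal(regional_lesion_volume(m2, atlas, reg)$volume_ml,
                 sum(m2$voxels[labels == lab]) / 1000)
  }
  cohort <- assemble_cohort(list(m, m2), make_behavior(c("s1", "s2")))
  vols <- regional_lesion_volumes(cohort, atlas)
  per_subject <- dplyr::summarise(dplyr::group_by(vols, subject_id),
                                  region_sum = sum(volume_ml),
                                  total = dplyr::first(total_lesion_ml))
  expect_true(all(per_subject$region_sum <= per_subject$total + 1e-12))

  # non-unit voxels scale by the voxel volume
  grid2 <- grid_geometry(c(12, 12, 12), voxel_size = 2)
  atlas2 <- atlas_volume(grid2, labels, atlas$region_table)
  m3 <- make_map("s3", grid2, 1:500)
  expect_equal(regional_lesion_volume(m3, atlas2, "A")$volume_ml, 500 * 8 / 1000)
})

test_that("hierarchical ROI regression reports delta-R2 via the partial F test", {
  set.seed(63)
  n <- 80
  d <- tibble::tibble(
    subject_id = sprintf("s%d", 1:n),
    age = runif(n, 40, 85), sex = rbinom(n, 1, 0.5),
    education = sample(1:7, n, TRUE),
    roi_ml = rexp(n, 1), total_ml = NA
  )
  d$total_ml <- d$roi_ml + rexp(n, 2)
  d$z <- -0.01 * d$age - 0.4 * d$roi_ml + rnorm(n, 0, 0.8)

  fit <- fit_roi_model(d, "z", "roi_ml")
  expect_gte(fit$r2_full, fit$r2_base)
  expect_true(fit$ci95[1] <= fit$B && fit$B <= fit$ci95[2])

  # partial F for one added regressor equals the coefficient's two-sided t test
  tt <- tidy(fit)
  expect_equal(fit$p_delta, unname(tt$p.value[tt$term == "roi_ml"]),
               tolerance = 1e-10)
  # and equals the from-scratch F formula on the two R2 values
  F_manual <- (fit$r2_full - fit$r2_base) / (1 - fit$r2_full) * (n - 5)
  expect_equal(fit$f_delta, F_manual, tolerance = 1e-8)
  expect_equal(fit$p_delta, pf(F_manual, 1, n - 5, lower.tail = FALSE),
               tolerance = 1e-10)

  # all-zero roi volume: full model collapses onto the base model
  d0 <- d; d0$roi_zero <- 0
  fit0 <- fit_roi_model(d0, "z", "roi_zero")
  expect_equal(fit0$r2_full, fit0$r2_base)
  expect_equal(fit0$p_delta, 1)
  expect_true(is.na(fit0$B))

  # adjusting for total volume changes the base model but keeps the contract
  fit_t <- fit_roi_model(d, "z", "roi_ml", total_volume = "total_ml")
  expect_true(fit_t$adjusted_for_total_volume)
  expect_gte(fit_t$r2_full, fit_t$r2_base)

  # collinearity is rejected with a diagnostic
  d_bad <- d; d_bad$dup <- d_bad$roi_ml
  expect_error(fit_roi_model(d_bad, "z", "dup", total_volume = "roi_ml"),
               "rank-deficient")

  # listwise deletion: n recorded
  d_na <- d; d_na$z[1:7] <- NA
  expect_equal(fit_roi_model(d_na, "z", "roi_ml")$n, n - 7)

  # tidy/glance surfaces
  expect_true(all(c("term", "estimate", "p.value") %in% names(tidy(fit))))
  g <- glance(fit)
  expect_equal(g$delta_r2, fit$r2_full - fit$r2_base)
})

test_that("ROI regression recovers a known per-ml coefficient", {
  set.seed(64)
  n <- 500
  d <- tibble::tibble(
    subject_id = sprintf("s%d", 1:n),
    age = runif(n, 40, 85), sex = rbinom(n, 1, 0.5),
    education = sample(1:7, n, TRUE),
    roi_ml = rexp(n, 0.7)
  )
  d$z <- 0.3 - 0.005 * d$age - 0.4 * d$roi_ml + rnorm(n, 0, 1)
  fit <- fit_roi_model(d, "z", "roi_ml")
  expect_true(fit$ci95[1] <= -0.4 && -0.4 <= fit$ci95[2])
  expect_equal(fit$B, -0.4, tolerance = 0.15)
})
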