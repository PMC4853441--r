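# deterministic cohort where voxel 1 is lesioned in exactly the first k
# subjects and scores are free to choose
vlsm_fixture <- function(z, lesioned_idx, n = length(z), grid = tiny_grid()) {
  idx_list <- purrr::map(seq_len(n), function(s) {
    v <- c(2, 3, 4)                      # shared background lesion
    if (s %in% lesioned_idx) v <- c(1, v)
    v
  })
  cohort <- make_cohort(idx_list)
  scores <- tibble::tibble(subject_id = cohort$subjects, z = z)
  list(cohort = cohort, scores = scores)
}

test_that("the test mask keeps voxels with enough lesioned and intact subjects", {
  grid <- tiny_grid()
  # voxel 1: count 2; voxel 2: count 3; voxel 3: count 4 (all subjects)
  cohort <- make_cohort(list(c(1, 2, 3), c(1, 2, 3), c(2, 3), c(3)))
  prev <- lesion_prevalence(cohort)
  mask <- build_test_mask(prev, min_count = 3)
  expect_false(mask$tested[1])   # lesioned in fewer than 3 patients
  expect_true(mask$tested[2])    # exactly 3: boundary is tested
  expect_false(mask$tested[3])   # lesioned in everyone: no intact group
  expect_equal(sum(mask$tested), 1)

  expect_warning(build_test_mask(lesion_prevalence(make_cohort(list(1, 2)))),
                 "empty")
})

test_that("voxel-wise t equals the from-scratch two-sample formula, with the lesion-deficit sign", {
  fx <- vlsm_fixture(z = c(-2, -1, 0, 1), lesioned_idx = 1:2)
  mask <- build_test_mask(lesion_prevalence(fx$cohort), min_count = 2)
  sm <- vlsm(fx$cohort, fx$scores, mask)
  expect_true(sm$tested[1])
  # lesioned z = {-2,-1}, intact z = {0,1}: worse performance -> positive t
  t_expected <- oracle_pooled_t(intact = c(0, 1), lesioned = c(-2, -1))
  expect_gt(sm$statistic[1], 0)
  expect_equal(sm$statistic[1], t_expected, tolerance = 1e-10)
  expect_equal(sm$df[1], 2)
  expect_equal(sm$p[1], pt(t_expected, 2, lower.tail = FALSE), tolerance = 1e-12)

  # identical group means: t = 0, one-tailed p = 0.5
  fx0 <- vlsm_fixture(z = c(-1, 1, -1, 1), lesioned_idx = 1:2)
  sm0 <- vlsm(fx0$cohort, fx0$scores,
              build_test_mask(lesion_prevalence(fx0$cohort), min_count = 2))
  expect_equal(sm0$statistic[1], 0)
  expect_equal(sm0$p[1], 0.5)

  # random instances vs oracle
  set.seed(41)
  for (rep in 1:10) {
    z <- rnorm(12)
    les <- sample(12, 5)
    fx_r <- vlsm_fixture(z, les)
    sm_r <- vlsm(fx_r$cohort, fx_r$scores,
                 build_test_mask(lesion_prevalence(fx_r$cohort), min_count = 3))
    expect_equal(sm_r$statistic[1], oracle_pooled_t(z[-les], z[les]),
                 tolerance = 1e-10)
  }
})

test_that("lesioned-better voxels get negative t and are never significant one-tailed", {
  # lesioned group clearly better
  fx <- vlsm_fixture(z = c(2, 2.5, 3, -1, -1.5, -2, 0, 0.3), lesioned_idx = 1:3)
  mask <- build_test_mask(lesion_prevalence(fx$cohort), min_count = 3)
  sm <- vlsm(fx$cohort, fx$scores, mask, q = 0.05)
  expect_lt(sm$statistic[1], 0)
  expect_false(sm$significant[1])
  expect_gt(sm$p[1], 0.5)
})

test_that("t maps are invariant to score shifts and equivariant under negation", {
  set.seed(42)
  z <- rnorm(10)
  fx <- vlsm_fixture(z, lesioned_idx = c(1, 4, 7))
  mask <- build_test_mask(lesion_prevalence(fx$cohort), min_count = 3)
  base <- vlsm(fx$cohort, fx$scores, mask)
  shift <- vlsm(fx$cohort, dplyr::mutate(fx$scores, z = z + 100), mask)
  expect_equal(shift$statistic[1], base$statistic[1], tolerance = 1e-9)
  neg <- vlsm(fx$cohort, dplyr::mutate(fx$scores, z = -z), mask)
  expect_equal(neg$statistic[1], -base$statistic[1], tolerance = 1e-9)
})

test_that("vectorized voxel statistics equal an explicit per-voxel loop", {
  set.seed(43)
  space <- toy_space(c(12, 12, 12))
  cohort <- simulate_fluency_cohort(n = 20, space = space,
                                    volume_range = c(10, 80), seed = 5)
  scores <- tibble::tibble(subject_id = cohort$subjects, z = rnorm(20))
  mask <- build_test_mask(lesion_prevalence(cohort), min_count = 3)
  sm <- vlsm(cohort, scores, mask)
  for (v in sample(which(sm$tested), 25)) {
    les <- cohort$lesions[, v] == 1L
    expect_equal(sm$statistic[v], oracle_pooled_t(scores$z[!les], scores$z[les]),
                 tolerance = 1e-10)
  }
})

test_that("Brunner-Munzel matches the placement-count oracle and is rank invariant", {
  set.seed(44)
  for (rep in 1:10) {
    z <- rnorm(14)
    les <- sample(14, 6)
    fx <- vlsm_fixture(z, les)
    mask <- build_test_mask(lesion_prevalence(fx$cohort), min_count = 3)
    sm <- vlsm(fx$cohort, fx$scores, mask, statistic = "brunner_munzel")
    o <- oracle_bm(x = z[les], y = z[-les])
    expect_equal(sm$statistic[1], o$statistic, tolerance = 1e-8)
    expect_equal(sm$df[1], o$df, tolerance = 1e-8)

    # monotone transform of the scores leaves the rank statistic unchanged
    sm2 <- vlsm(fx$cohort, dplyr::mutate(fx$scores, z = exp(z)), mask,
                statistic = "brunner_munzel")
    expect_equal(sm2$statistic[1], sm$statistic[1], tolerance = 1e-10)
  }

  # identical samples in both groups: statistic 0
  fx_t <- vlsm_fixture(z = rep(c(1, 2), 4), lesioned_idx = c(1, 2, 3, 4))
  mask_t <- build_test_mask(lesion_prevalence(fx_t$cohort), min_count = 3)
  sm_t <- vlsm(fx_t$cohort, fx_t$scores, mask_t, statistic = "brunner_munzel")
  expect_equal(sm_t$statistic[1], 0)
  expect_equal(sm_t$p[1], 0.5)

  # fully tied scores: degenerate voxel flagged, p = 1
  fx_c <- vlsm_fixture(z = rep(2, 8), lesioned_idx = 1:4)
  sm_c <- vlsm(fx_c$cohort, fx_c$scores,
               build_test_mask(lesion_prevalence(fx_c$cohort), min_count = 3),
               statistic = "brunner_munzel")
  expect_equal(sm_c$statistic[1], 0)
  expect_equal(sm_c$p[1], 1)
  expect_true(sm_c$zero_variance[1])
})

test_that("BH step-up matches hand-computed and looped oracles", {
  # all p tiny: everything significant
  all_small <- fdr_threshold(rep(0.001, 100), q = 0.05)
  expect_true(all(all_small$significant))

  # hand-computed: p = {0.01, 0.02, 0.9, 0.95}, m = 4, q = 0.05
  # k=1: 0.01 <= 0.0125 yes; k=2: 0.02 <= 0.025 yes; k=3: 0.9 > 0.0375
  hand <- fdr_threshold(c(0.01, 0.02, 0.9, 0.95), q = 0.05)
  expect_equal(hand$significant, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(hand$cutoff, 0.02)

  # no rejection: empty set and cutoff 0
  none <- fdr_threshold(c(0.5, 0.9), q = 0.05)
  expect_false(any(none$significant))
  expect_equal(none$cutoff, 0)

  # random instances vs the explicit step-up loop
  set.seed(45)
  for (rep in 1:20) {
    p <- runif(50)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    got <- fdr_threshold(p, q)
    want <- oracle_bh(p, q)
    expect_equal(got$significant, want$significant)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("the significance set grows monotonically with q", {
  set.seed(46)
  p <- runif(200)^2
  qs <- c(0.01, 0.05, 0.1, 0.2)
  sets <- purrr::map(qs, ~ which(fdr_threshold(p, .x)$significant))
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("overlap maps classify voxels by joint significance", {
  space <- toy_space(c(12, 12, 12))
  cohort <- simulate_fluency_cohort(n = 24, space = space,
                                    volume_range = c(10, 80), seed = 6)
  mask <- build_test_mask(lesion_prevalence(cohort), min_count = 3)
  set.seed(47)
  smA <- vlsm(cohort, tibble::tibble(subject_id = cohort$subjects, z = rnorm(24)),
              mask, outcome = "A")
  smB <- vlsm(cohort, tibble::tibble(subject_id = cohort$subjects, z = rnorm(24)),
              mask, outcome = "B")
  # plant synthetic significance patterns and check the set algebra
  smA$significant[] <- FALSE; smB$significant[] <- FALSE
  smA$significant[1:60] <- TRUE
  smB$significant[41:100] <- TRUE
  ov <- overlap_map(smA, smB)
  expect_equal(sum(ov$category == 3L), 20)        # both: 41..60
  expect_equal(sum(ov$category == 1L), 40)        # A-only
  expect_equal(sum(ov$category == 2L), 40)        # B-only
  expect_equal(which(ov$category == 3L), 41:60)

  # identical sets: every significant voxel is "both"
  ov_same <- overlap_map(smA, smA)
  expect_equal(sum(ov_same$category == 3L), sum(smA$significant))
  expect_equal(sum(ov_same$category %in% c(1L, 2L)), 0)

  # grid mismatch rejected
  other <- simulate_fluency_cohort(n = 10, space = toy_space(c(10, 10, 10)),
                                   volume_range = c(5, 20), seed = 8)
  maskO <- build_test_mask(lesion_prevalence(other), min_count = 2)
  smO <- vlsm(other, tibble::tibble(subject_id = other$subjects, z = rnorm(10)),
              maskO)
  expect_error(overlap_map(smA, smO), "grid mismatch")
})

test_that("zero-variance voxels yield p = 1 and stay in the map", {
  fx <- vlsm_fixture(z = rep(3, 8), lesioned_idx = 1:4)
  mask <- build_test_mask(lesion_prevalence(fx$cohort), min_count = 3)
  sm <- vlsm(fx$cohort, fx$scores, mask)
  expect_equal(sm$statistic[1], 0)
  expect_equal(sm$p[1], 1)
  expect_true(sm$zero_variance[1])
  expect_true(sm$tested[1])
})
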