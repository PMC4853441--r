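#' Deterministic toy brain space with template mask and atlas
#'
#' Builds a small stand-in for a template brain: an ellipsoidal brain mask on
#' a centered grid, a supratentorial/infratentorial compartment split, a
#' hemisphere coding (world x < 0 left, > 0 right; the midline falls between
#' voxels so no voxel sits on it), and a box-shaped atlas of labeled regions
#' spanning left/right frontal and temporal analogues plus an infratentorial
#' analogue. Entirely deterministic: the same dimensions always give the same
#' volumes.
#'
#' @param dims Voxels per axis (default 32^3; each axis >= 8).
#' @param voxel_size mm per voxel (default 2, a half-resolution analogue of a
#'   1 mm template at this grid size).
#' @return A `toy_space`: `grid`, `mask` (logical 3D), `compartments`
#'   (integer 3D: 0 outside, 1 supratentorial, 2 infratentorial),
#'   `hemisphere` (integer 3D: -1 left, +1 right), `atlas` (`atlas_volume`).
#' @export
toy_space <- function(dims = c(32, 32, 32), voxel_size = 2) {
  dims <- as.integer(rep_len(dims, 3))
  assert_that(all(dims >= 8), "toy space needs at least 8 voxels per axis")
  grid <- grid_geometry(dims, voxel_size, space_label = "toy")

  # ellipsoidal brain mask in voxel coordinates (1-based centers)
  ci <- (dims + 1) / 2
  ri <- dims / 2 - 0.55
  ax <- function(a) (seq_len(dims[a]) - ci[a]) / ri[a]
  d2 <- outer(outer(ax(1)^2, ax(2)^2, `+`), ax(3)^2, `+`)
  mask <- d2 <= 1

  infr_k <- max(2L, round(dims[3] * 0.22))   # bottom slab = infratentorial analogue
  kk <- array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dim = dims)
  compartments <- array(0L, dim = dims)
  compartments[mask & kk > infr_k] <- 1L
  compartments[mask & kk <= infr_k] <- 2L

  hemi <- array(ifelse(world_x_array(grid) < 0, -1L, 1L), dim = dims)

  # box regions (voxel index ranges, then intersected with the supratentorial
  # mask); fractions of each axis keep the layout valid for any dims
  f <- function(a, lo, hi) {
    r <- round(c(lo, hi) * dims[a])
    seq(max(1, r[1]), min(dims[a], r[2]))
  }
  left <- f(1, 0.10, 0.47); right <- f(1, 0.53, 0.90)
  frontal_j <- f(2, 0.58, 0.90); temporal_j <- f(2, 0.28, 0.56)
  upper_k <- f(3, 0.62, 0.86); mid_k <- f(3, 0.38, 0.60); low_k <- f(3, 0.24, 0.46)

  labels <- array(0L, dim = dims)
  put <- function(labels, label, ii, jj, kk_rng) {
    sub <- as.matrix(expand.grid(ii, jj, kk_rng))
    keep <- compartments[sub] == 1L & labels[sub] == 0L
    labels[sub[keep, , drop = FALSE]] <- label
    labels
  }
  labels <- put(labels, 1L, left, frontal_j, upper_k)      # left middle frontal
  labels <- put(labels, 2L, left, frontal_j, mid_k)        # left inferior frontal
  labels <- put(labels, 3L, left, temporal_j, low_k)       # left temporal
  labels <- put(labels, 4L, left, f(2, 0.12, 0.26), upper_k) # left parietal
  labels <- put(labels, 5L, right, frontal_j, c(mid_k, upper_k)) # right frontal
  labels <- put(labels, 6L, right, temporal_j, low_k)      # right temporal
  infra_idx <- which(compartments == 2L)
  labels[infra_idx] <- 7L                                  # infratentorial analogue

  region_table <- tibble(
    label = 1:7,
    region = c("left middle frontal", "left inferior frontal", "left temporal",
               "left parietal", "right frontal", "right temporal",
               "infratentorial")
  )
  structure(
    list(grid = grid, mask = mask, compartments = compartments,
         hemisphere = hemi, atlas = atlas_volume(grid, labels, region_table)),
    class = "toy_space"
  )
}

#' @export
print.toy_space <- function(x, ...) {
  cat(sprintf("<toy_space> %s voxels (%g mm), %d brain voxels, %d atlas regions\n",
              paste(x$grid$dims, collapse = "x"), x$grid$voxel_size[1],
              sum(x$mask), nrow(x$atlas$region_table)))
  invisible(x)
}

#' Simulate spatially contiguous unilateral lesions
#'
#' Grows each lesion as a single 6-connected component by stochastic region
#' growing (iteratively adding a random boundary voxel), which produces
#' irregular, territory-like shapes closer to infarcts than spherical blobs.
#' Each lesion is confined to one site: the supratentorial left or right
#' hemisphere, the infratentorial compartment, or (rarely) grown from a
#' paramedian seed across both hemispheres ("bilateral"). Site frequencies
#' default to the territory-like prevalence of a first-ever ischemic stroke
#' cohort, with right-hemisphere lesions slightly more frequent than left.
#'
#' @param space A `toy_space` (or compatible list with `grid`, `mask`,
#'   `compartments`, `hemisphere`).
#' @param n Number of subjects.
#' @param volume_range Lesion size range in voxels, sampled uniformly.
#' @param site_probs Named probabilities for sites
#'   `left`, `right`, `infratentorial`, `bilateral` (normalized internally).
#' @param subject_ids Identifiers (default `s001`, `s002`, ...).
#' @param seed Optional integer seed (`set.seed` is called when given).
#' @return List of `lesion_map`s with an attached tibble
#'   `attr(., "sites")` giving each subject's generative site.
#' @export
simulate_lesions <- function(space, n, volume_range = c(50, 800),
                             site_probs = c(left = 0.37, right = 0.43,
                                            infratentorial = 0.12, bilateral = 0.08),
                             subject_ids = sprintf("s%03d", seq_len(n)),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_that(length(volume_range) == 2 && volume_range[1] >= 1 &&
                volume_range[1] <= volume_range[2],
              "invalid lesion volume range")
  site_probs <- site_probs / sum(site_probs)
  dims <- space$grid$dims
  allowed_for <- list(
    left = space$compartments == 1L & space$hemisphere < 0L,
    right = space$compartments == 1L & space$hemisphere > 0L,
    infratentorial = space$compartments == 2L,
    bilateral = space$compartments == 1L
  )
  for (site in names(site_probs)) {
    if (site_probs[site] > 0 && volume_range[2] > sum(allowed_for[[site]])) {
      stop_fm("volume range [%d, %d] unattainable at site '%s' (%d voxels available)",
              volume_range[1], volume_range[2], site, sum(allowed_for[[site]]))
    }
  }
  paramedian <- abs(world_x_array(space$grid)) <= 1.5 * space$grid$voxel_size[1]

  sites <- sample(names(site_probs), n, replace = TRUE, prob = site_probs)
  maps <- purrr::map(seq_len(n), function(s) {
    allowed <- allowed_for[[sites[s]]]
    seed_pool <- if (sites[s] == "bilateral") which(allowed & paramedian) else which(allowed)
    target <- as.integer(round(stats::runif(1, volume_range[1], volume_range[2])))
    for (try in 1:25) {
      seed_voxel <- if (length(seed_pool) == 1) seed_pool else sample(seed_pool, 1)
      idx <- grow_lesion_cpp(as.logical(allowed), dims, seed_voxel, target)
      if (length(idx) == target) break
    }
    assert_that(length(idx) == target,
                "lesion growth stalled for subject %s at site %s", subject_ids[s], sites[s])
    vox <- array(0L, dim = dims)
    vox[idx] <- 1L
    lesion_map(subject_ids[s], space$grid, vox)
  })
  attr(maps, "sites") <- tibble(subject_id = subject_ids, site = sites)
  maps
}

#' Default generative effect model for synthetic behavior
#'
#' One entry per test column. Each raw score is generated on the count scale
#' as `baseline + age_beta*(age-60) + sex_beta*sex + edu_beta*(education-5)
#' + sum_r weight_r * (lesioned ml in region r) + Normal(0, sd)`, then
#' clipped at 0 and rounded. The two causal fluency regions form a double
#' dissociation: the left temporal analogue lowers only the animal (semantic)
#' count; the left middle frontal analogue lowers only the letter (phonemic)
#' counts. Baselines, spreads and demographic gradients approximate a
#' first-ever stroke cohort in its sixties (animals about 23 +/- 10 in 2 min,
#' letters about 8 +/- 4 per minute each).
#'
#' @return Named list of per-test parameter lists (`baseline`, `weights`
#'   in raw points per ml of regional lesion, `age_beta`, `sex_beta`,
#'   `edu_beta`, `sd`, `missing_rate`).
#' @export
default_effects <- function() {
  list(
    animals_2min = list(baseline = 24, weights = c("left temporal" = -9),
                        age_beta = -0.12, sex_beta = 1.0, edu_beta = 1.2,
                        sd = 6, missing_rate = 0),
    letterN_1min = list(baseline = 8, weights = c("left middle frontal" = -3.5),
                        age_beta = -0.05, sex_beta = 0.4, edu_beta = 0.5,
                        sd = 3, missing_rate = 0),
    letterA_1min = list(baseline = 8.3, weights = c("left middle frontal" = -3.5),
                        age_beta = -0.05, sex_beta = 0.4, edu_beta = 0.5,
                        sd = 3, missing_rate = 0),
    ravlt_total = list(baseline = 40, weights = c("left temporal" = -6),
                       age_beta = -0.35, sex_beta = -2, edu_beta = 1.5,
                       sd = 9, missing_rate = 4 / 93),
    rocf_delayed = list(baseline = 16, weights = c("right temporal" = -4),
                        age_beta = -0.12, sex_beta = 0.5, edu_beta = 0.8,
                        sd = 6, missing_rate = 8 / 93),
    boston_naming = list(baseline = 26, weights = c("left temporal" = -2.5,
                                                    "left inferior frontal" = -2.5),
                         age_beta = -0.04, sex_beta = 0.3, edu_beta = 0.6,
                         sd = 2.5, missing_rate = 2 / 93),
    token_test = list(baseline = 19.5, weights = c("left inferior frontal" = -3),
                      age_beta = -0.02, sex_beta = 0.1, edu_beta = 0.3,
                      sd = 1.5, missing_rate = 8 / 93)
  )
}

#' Simulate cohort demographics
#'
#' Age approximately normal around 59.5 (sd 14.9) truncated to 18-90, sex
#' coded 1 = male with probability 0.57, education on the ordinal 1-7 scale
#' centered on category 5.
#'
#' @param n Number of subjects.
#' @param subject_ids Identifiers.
#' @param seed Optional seed.
#' @return Tibble with `subject_id`, `age`, `sex`, `education`.
#' @export
simulate_demographics <- function(n, subject_ids = sprintf("s%03d", seq_len(n)),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble(
    subject_id = subject_ids,
    age = round(pmin(pmax(stats::rnorm(n, 59.5, 14.9), 18), 90)),
    sex = stats::rbinom(n, 1, 0.57),
    education = sample(1:7, n, replace = TRUE,
                       prob = c(0.02, 0.08, 0.15, 0.20, 0.30, 0.15, 0.10))
  )
}

# per-subject lesion ml within each atlas region (matrix subjects x regions)
region_ml_matrix <- function(lesion_maps, atlas) {
  vv <- voxel_volume_ml(atlas$grid)
  lab_vec <- as.integer(atlas$labels)
  vapply(atlas$region_table$label, function(l) {
    idx <- which(lab_vec == l)
    vapply(lesion_maps, function(m) sum(m$voxels[idx]) * vv, numeric(1))
  }, numeric(length(lesion_maps)))
}

#' Simulate behavior from lesions, ground-truth weights and demographics
#'
#' Applies the generative model documented in [default_effects()]: lesion
#' load (ml) in each causal region lowers the raw count, demographics shift
#' it, Gaussian noise is added, and the result is clipped at zero and rounded
#' to an integer count. Per-test missingness is then applied completely at
#' random at the configured rate.
#'
#' @param lesion_maps List of `lesion_map`s.
#' @param atlas `atlas_volume` naming the causal regions.
#' @param demographics Tibble from [simulate_demographics()].
#' @param effects Effect model (default [default_effects()]).
#' @param seed Optional seed.
#' @return Behavior tibble: `subject_id`, `age`, `sex`, `education`, one
#'   column per test.
#' @export
simulate_behavior <- function(lesion_maps, atlas, demographics,
                              effects = default_effects(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(lesion_maps)
  assert_that(n == nrow(demographics), "lesion maps and demographics differ in size")
  ml <- region_ml_matrix(lesion_maps, atlas)
  colnames(ml) <- atlas$region_table$region
  out <- demographics
  for (test in names(effects)) {
    e <- effects[[test]]
    lesion_term <- rep(0, n)
    for (r in names(e$weights)) {
      assert_that(r %in% colnames(ml), "unknown causal region '%s' for test %s", r, test)
      lesion_term <- lesion_term + e$weights[[r]] * ml[, r]
    }
    raw <- e$baseline + e$age_beta * (demographics$age - 60) +
      e$sex_beta * demographics$sex + e$edu_beta * (demographics$education - 5) +
      lesion_term + stats::rnorm(n, 0, e$sd)
    raw <- round(pmax(raw, 0))
    if (e$missing_rate > 0) raw[stats::runif(n) < e$missing_rate] <- NA
    out[[test]] <- raw
  }
  out
}

#' Normative cutoffs for the synthetic effect model
#'
#' Simulates a large lesion-free ("healthy") reference sample from the same
#' generative model — demographic variation plus noise, no lesion term — and
#' takes the 5th percentile of each test's score distribution as the
#' dichotomization cutoff. Also provides cutoffs for the derived `semantic`
#' (animal count) and `phonemic` (N + A) scores.
#'
#' @param effects Effect model (default [default_effects()]).
#' @param n Reference sample size (default 10000).
#' @param seed Seed for the reference draw (default 20150505, fixed so the
#'   norms are stable package-wide).
#' @param percentile Normative percentile (default 0.05).
#' @return Norm tibble with `test`, `cutoff`.
#' @export
synthetic_norm_table <- function(effects = default_effects(), n = 10000,
                                 seed = 20150505, percentile = 0.05) {
  set.seed(seed)
  demo <- simulate_demographics(n, seed = NULL)
  scores <- demo
  for (test in names(effects)) {
    e <- effects[[test]]
    raw <- e$baseline + e$age_beta * (demo$age - 60) + e$sex_beta * demo$sex +
      e$edu_beta * (demo$education - 5) + stats::rnorm(n, 0, e$sd)
    scores[[test]] <- round(pmax(raw, 0))
  }
  scores$semantic <- scores$animals_2min
  scores$phonemic <- combine_phonemic(scores$letterN_1min, scores$letterA_1min)
  tests <- c(setdiff(names(effects), character(0)), "semantic", "phonemic")
  tibble(test = tests,
         cutoff = vapply(tests, function(t) unname(stats::quantile(scores[[t]], percentile)),
                         numeric(1)))
}

#' Simulate a complete synthetic fluency cohort with ground truth
#'
#' The one-call generator: toy space, territory-like lesions, demographics,
#' behavior from ground-truth voxel weights plus demographic effects and
#' noise, assembled into a validated `lesion_cohort` with the atlas attached.
#' The generative truth (causal regions, weight volumes, coefficients) is
#' stored in `$truth`, which no analysis stage reads; the generative lesion
#' site of each subject is in `$truth$sites`. Fully deterministic under a
#' fixed seed.
#'
#' @param n Number of subjects (default 93, the size of a single-center
#'   first-ever stroke cohort this generator emulates).
#' @param space A `toy_space` (default [toy_space()]).
#' @param effects Effect model (default [default_effects()]); set all
#'   `weights` to zero for a global-null cohort.
#' @param volume_range,site_probs Passed to [simulate_lesions()].
#' @param seed Integer seed governing the whole draw.
#' @return A `lesion_cohort` with `$atlas`, `$compartments`, `$norms`
#'   (from [synthetic_norm_table()]) and `$truth`.
#' @export
simulate_fluency_cohort <- function(n = 93, space = toy_space(),
                                    effects = default_effects(),
                                    volume_range = c(50, 800),
                                    site_probs = c(left = 0.37, right = 0.43,
                                                   infratentorial = 0.12,
                                                   bilateral = 0.08),
                                    seed = 1) {
  assert_that(n >= 4, "need at least 4 subjects")
  set.seed(seed)
  maps <- simulate_lesions(space, n, volume_range = volume_range,
                           site_probs = site_probs, seed = NULL)
  demo <- simulate_demographics(n, seed = NULL)
  behavior <- simulate_behavior(maps, space$atlas, demo, effects, seed = NULL)
  cohort <- assemble_cohort(maps, behavior, atlas = space$atlas)
  cohort$compartments <- space$compartments
  cohort$norms <- synthetic_norm_table(effects)
  cohort$truth <- synthetic_truth(space, effects, attr(maps, "sites"))
  cohort
}

# package the generative truth: per-outcome weight volumes + coefficients
synthetic_truth <- function(space, effects, sites) {
  rt <- space$atlas$region_table
  weight_volume <- function(weights) {
    w <- array(0, dim = space$grid$dims)
    for (r in names(weights)) {
      w[space$atlas$labels == rt$label[rt$region == r]] <- weights[[r]]
    }
    w
  }
  semantic_w <- effects$animals_2min$weights
  phonemic_w <- c(effects$letterN_1min$weights, effects$letterA_1min$weights)
  phonemic_w <- tapply(phonemic_w, names(phonemic_w), sum)
  list(
    weights_ml = list(semantic = as.list(semantic_w),
                      phonemic = as.list(phonemic_w)),
    weight_volumes = list(semantic = weight_volume(as.list(semantic_w)),
                          phonemic = weight_volume(as.list(phonemic_w))),
    causal_regions = list(semantic = names(semantic_w),
                          phonemic = unique(names(phonemic_w))),
    demographics = purrr::map(effects, ~ .x[c("age_beta", "sex_beta", "edu_beta")]),
    noise_sd = purrr::map_dbl(effects, "sd"),
    baselines = purrr::map_dbl(effects, "baseline"),
    sites = sites
  )
}
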