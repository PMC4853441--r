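#' Build the tested-voxel mask
#'
#' Voxels lesioned in fewer than `min_count` patients are not tested (too few
#' lesioned subjects to compare groups); voxels lesioned in *all* subjects are
#' likewise excluded because the intact group would be empty. No separate
#' brain mask is applied — the lesion-count threshold subsumes it, since
#' voxels outside the brain are never lesioned.
#'
#' @param prevalence A `count_map` from [lesion_prevalence()].
#' @param min_count Minimum number of lesioned patients per voxel (default 3).
#' @return A `test_mask`: `grid`, `tested` (logical 3D array), `min_count`,
#'   `n_subjects`. An empty mask triggers a warning; downstream analyses
#'   reject it.
#' @export
build_test_mask <- function(prevalence, min_count = 3) {
  assert_that(min_count >= 1, "min_count must be >= 1")
  n <- prevalence$n_subjects
  tested <- prevalence$counts >= min_count & prevalence$counts <= n - 1L
  if (!any(tested)) warn("test mask is empty: no voxel reaches the lesion-count threshold")
  structure(list(grid = prevalence$grid, tested = tested,
                 min_count = min_count, n_subjects = n),
            class = "test_mask")
}

#' @export
print.test_mask <- function(x, ...) {
  cat(sprintf("<test_mask> %d tested voxels (lesion count >= %d of %d subjects)\n",
              sum(x$tested), x$min_count, x$n_subjects))
  invisible(x)
}

#' Benjamini-Hochberg threshold over a set of p values
#'
#' Step-up FDR control at level `q`: the realized cutoff is the largest
#' p(k) with p(k) <= k q / m; all p at or below it are significant. With no
#' qualifying k the significance set is empty and the cutoff 0.
#'
#' @param p Numeric vector of p values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `cutoff` (realized p cutoff), `significant` (logical,
#'   aligned with `p`), `q`, `m` (number of tests).
#' @export
fdr_threshold <- function(p, q = 0.05) {
  assert_that(length(p) > 0, "empty p-value collection")
  assert_that(all(p >= 0 & p <= 1), "p values must lie in [0, 1]")
  significant <- stats::p.adjust(p, method = "BH") <= q
  cutoff <- if (any(significant)) max(p[significant]) else 0
  list(cutoff = cutoff, significant = significant, q = q, m = length(p))
}

# pooled- or Welch-variance two-sample t over many voxels at once.
# lesions: n x m 0/1 matrix; z: length-n outcome. Returns per-voxel lists.
# Sign convention: positive t = lesioned group performs worse (lower z).
vectorized_group_t <- function(lesions, z, var_equal = TRUE) {
  n <- length(z)
  n1 <- colSums(lesions)                    # lesioned
  n0 <- n - n1                              # intact
  s1 <- as.numeric(crossprod(lesions, z))
  q1 <- as.numeric(crossprod(lesions, z^2))
  S <- sum(z); Q <- sum(z^2)
  m1 <- s1 / n1
  m0 <- (S - s1) / n0
  ss1 <- q1 - n1 * m1^2                     # within-group sums of squares
  ss0 <- (Q - q1) - n0 * m0^2
  ss1 <- pmax(ss1, 0); ss0 <- pmax(ss0, 0)  # clamp tiny negatives (float)
  if (var_equal) {
    sp2 <- (ss1 + ss0) / (n - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n - 2, length(n1))
  } else {
    v1 <- ss1 / (n1 - 1); v0 <- ss0 / (n0 - 1)
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  zero_var <- !is.finite(se) | se <= 0
  stat <- ifelse(zero_var, 0, (m0 - m1) / se)
  list(statistic = stat, df = df, n1 = n1, n0 = n0, zero_variance = zero_var)
}

# Brunner-Munzel rank statistic for one voxel; positive = intact ranks higher
# (lesioned performs worse). Returns c(statistic, df); df NA when degenerate.
bm_stat <- function(z_lesioned, z_intact) {
  n1 <- length(z_lesioned); n0 <- length(z_intact); N <- n1 + n0
  rk <- rank(c(z_lesioned, z_intact))       # midranks
  r1 <- rk[seq_len(n1)]; r0 <- rk[n1 + seq_len(n0)]
  rb1 <- mean(r1); rb0 <- mean(r0)
  s1 <- sum((r1 - rank(z_lesioned) - rb1 + (n1 + 1) / 2)^2) / (n1 - 1)
  s0 <- sum((r0 - rank(z_intact) - rb0 + (n0 + 1) / 2)^2) / (n0 - 1)
  denom <- N * sqrt(n1 * s1 + n0 * s0)
  if (denom <= 0) {
    if (rb0 == rb1) return(c(statistic = 0, df = NA_real_))
    return(c(statistic = sign(rb0 - rb1) * Inf, df = NA_real_))
  }
  stat <- n1 * n0 * (rb0 - rb1) / denom
  df <- (n1 * s1 + n0 * s0)^2 /
    ((n1 * s1)^2 / (n1 - 1) + (n0 * s0)^2 / (n0 - 1))
  c(statistic = stat, df = df)
}

#' Voxel-based lesion-symptom mapping
#'
#' At every tested voxel, compares the adjusted behavioral score between
#' subjects with and without a lesion there, using either the pooled-variance
#' two-sample t test (the default, as in the classic VLSM implementation) or
#' the non-parametric Brunner-Munzel rank statistic. Statistics are signed so
#' that positive values mean the lesioned group performs *worse*; inference is
#' one-tailed in that lesion-deficit direction by default (negative statistics
#' can then never be significant), with a two-tailed mode available.
#' Multiple testing over the tested voxels is controlled by
#' Benjamini-Hochberg FDR at level `q`.
#'
#' Subjects with a missing score are excluded from the analysis of that
#' outcome (equivalently, voxel-wise — the same subjects are missing at every
#' voxel). Voxels where the remaining subjects leave either group empty are
#' dropped from the tested set for this outcome. Voxels with zero variance
#' yield statistic 0 and p = 1 and are flagged, keeping the map total.
#'
#' @param cohort A `lesion_cohort`.
#' @param scores Data frame with `subject_id` and a score column (typically
#'   the z scores of one test from [adjust_for_demographics()]).
#' @param mask A `test_mask` from [build_test_mask()].
#' @param statistic `"t"` (pooled-variance Student t) or `"brunner_munzel"`.
#' @param q FDR level (default 0.05).
#' @param tails `"one"` (default, lesion-deficit direction) or `"two"`.
#' @param score_col Name of the score column (default `"z"`).
#' @param var_equal For the t statistic: pooled variance (default `TRUE`) or
#'   Welch.
#' @param outcome Label stored in the result (defaults to the score column).
#' @return A `stat_map`: `grid`; 3D arrays `statistic`, `p`, `df`,
#'   `tested`, `significant`, `zero_variance` (untested voxels carry `NA`);
#'   plus `fdr_cutoff`, `q`, `statistic_kind`, `tails`, `n_used`,
#'   `n_lesioned_range`, `outcome`.
#' @export
vlsm <- function(cohort, scores, mask, statistic = c("t", "brunner_munzel"),
                 q = 0.05, tails = c("one", "two"), score_col = "z",
                 var_equal = TRUE, outcome = NULL) {
  statistic <- match.arg(statistic)
  tails <- match.arg(tails)
  check_same_grid(cohort$grid, mask$grid, "test mask")
  assert_that(any(mask$tested), "empty test mask: nothing to analyze")
  scores <- as_tibble(scores)
  assert_that(all(c("subject_id", score_col) %in% names(scores)),
              "scores must have subject_id and '%s'", score_col)
  if ("test" %in% names(scores) && length(unique(scores$test)) > 1) {
    stop_fm("scores contain multiple tests; filter to one outcome first")
  }
  outcome <- outcome %||%
    (if ("test" %in% names(scores)) unique(scores$test)) %||% score_col

  z_all <- scores[[score_col]][match(cohort$subjects, scores$subject_id)]
  keep <- !is.na(z_all)
  assert_that(sum(keep) >= 4, "fewer than 4 subjects with a non-missing score")
  z <- z_all[keep]
  tested_idx <- which(mask$tested)
  L <- cohort$lesions[keep, tested_idx, drop = FALSE]

  n1 <- colSums(L)
  usable <- n1 >= 1 & n1 <= length(z) - 1   # both groups non-empty after drops
  tested_idx <- tested_idx[usable]
  L <- L[, usable, drop = FALSE]
  assert_that(length(tested_idx) > 0, "no voxel retains both groups after missing-score exclusion")

  if (statistic == "t") {
    res <- vectorized_group_t(L, z, var_equal = var_equal)
  } else {
    per <- apply(L, 2, function(les) bm_stat(z[les == 1L], z[les == 0L]))
    stat <- per["statistic", ]; df <- per["df", ]
    res <- list(statistic = stat, df = df,
                n1 = colSums(L), n0 = length(z) - colSums(L),
                zero_variance = stat == 0 & is.na(df))
  }
  p <- p_from_stat(res$statistic, res$df, tails)
  p[res$zero_variance] <- 1
  res$statistic[res$zero_variance] <- 0

  fdr <- fdr_threshold(p, q = q)

  dims <- cohort$grid$dims
  blank <- array(NA_real_, dim = dims)
  stat_arr <- blank; stat_arr[tested_idx] <- res$statistic
  p_arr <- blank; p_arr[tested_idx] <- p
  df_arr <- blank; df_arr[tested_idx] <- res$df
  tested_arr <- array(FALSE, dim = dims); tested_arr[tested_idx] <- TRUE
  sig_arr <- array(FALSE, dim = dims); sig_arr[tested_idx] <- fdr$significant
  zv_arr <- array(FALSE, dim = dims); zv_arr[tested_idx] <- res$zero_variance

  structure(
    list(grid = cohort$grid, statistic = stat_arr, p = p_arr, df = df_arr,
         tested = tested_arr, significant = sig_arr, zero_variance = zv_arr,
         fdr_cutoff = fdr$cutoff, q = q, statistic_kind = statistic,
         tails = tails, var_equal = var_equal, n_used = length(z),
         n_lesioned_range = range(res$n1), outcome = outcome,
         small_group_caveat = statistic == "brunner_munzel" && min(res$n1, res$n0) < 10),
    class = "stat_map"
  )
}

p_from_stat <- function(stat, df, tails) {
  p1 <- stats::pt(stat, df, lower.tail = FALSE)
  # degenerate (infinite-magnitude) statistics: df is NA; direction decides
  inf_pos <- is.na(df) & stat > 0
  inf_neg <- is.na(df) & stat < 0
  if (tails == "one") {
    p1[inf_pos] <- 0; p1[inf_neg] <- 1
    p1
  } else {
    p2 <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    p2[inf_pos | inf_neg] <- 0
    pmin(p2, 1)
  }
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s | %s statistic, %s-tailed | %d tested voxels, %d significant (q = %g, realized p cutoff %.3g)\n",
              x$outcome, x$statistic_kind, x$tails, sum(x$tested),
              sum(x$significant), x$q, x$fdr_cutoff))
  invisible(x)
}

#' @rdname tidy.count_map
#' @export
tidy.stat_map <- function(x, ...) {
  voxel_tibble(x$grid,
               list(statistic = x$statistic, p = x$p, df = x$df,
                    significant = x$significant),
               keep = x$tested)
}

#' @export
glance.stat_map <- function(x, ...) {
  tibble(outcome = x$outcome, statistic_kind = x$statistic_kind, tails = x$tails,
         n = x$n_used, n_tested_voxels = sum(x$tested),
         n_significant_voxels = sum(x$significant),
         q = x$q, fdr_cutoff = x$fdr_cutoff)
}

#' Conjunction/overlap of two significance maps
#'
#' Classifies every voxel as significant in neither map, only the first, only
#' the second, or both — the comparison used to show shared versus distinct
#' anatomical correlates of two outcomes.
#'
#' @param map_a,map_b `stat_map` objects on the same grid.
#' @return An `overlap_map` with a `category` 3D factor-coded integer array
#'   (0 none, 1 A-only, 2 B-only, 3 both), plus outcome labels and counts.
#' @export
overlap_map <- function(map_a, map_b) {
  check_same_grid(map_a$grid, map_b$grid, "overlap input")
  cat_arr <- array(0L, dim = map_a$grid$dims)
  cat_arr[map_a$significant & !map_b$significant] <- 1L
  cat_arr[!map_a$significant & map_b$significant] <- 2L
  cat_arr[map_a$significant & map_b$significant] <- 3L
  structure(
    list(grid = map_a$grid, category = cat_arr,
         outcomes = c(a = map_a$outcome, b = map_b$outcome),
         counts = c(none = sum(cat_arr == 0L), a_only = sum(cat_arr == 1L),
                    b_only = sum(cat_arr == 2L), both = sum(cat_arr == 3L))),
    class = "overlap_map"
  )
}

#' @export
print.overlap_map <- function(x, ...) {
  cat(sprintf("<overlap_map> %s vs %s: %d A-only, %d B-only, %d both\n",
              x$outcomes["a"], x$outcomes["b"],
              x$counts["a_only"], x$counts["b_only"], x$counts["both"]))
  invisible(x)
}

#' @rdname tidy.count_map
#' @export
tidy.overlap_map <- function(x, ...) {
  out <- voxel_tibble(x$grid, list(code = x$category), keep = x$category > 0L)
  out$category <- factor(c("a_only", "b_only", "both")[out$code],
                         levels = c("a_only", "b_only", "both"))
  out$code <- NULL
  out
}

#' Write a stat map as NIfTI volumes plus a JSON sidecar
#'
#' Emits `<prefix>_stat.nii.gz`, `<prefix>_p.nii.gz`,
#' `<prefix>_sig.nii.gz` and `<prefix>.json` (q, realized cutoff, statistic
#' kind, tails, n).
#'
#' @param x A `stat_map`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_stat_map <- function(x, prefix) {
  write_volume(ifelse(is.na(x$statistic), 0, x$statistic), x$grid,
               paste0(prefix, "_stat.nii.gz"))
  write_volume(ifelse(is.na(x$p), 1, x$p), x$grid, paste0(prefix, "_p.nii.gz"))
  write_volume(x$significant * 1L, x$grid, paste0(prefix, "_sig.nii.gz"))
  jsonlite::write_json(
    list(outcome = x$outcome, statistic_kind = x$statistic_kind, tails = x$tails,
         q = x$q, fdr_cutoff = x$fdr_cutoff, n = x$n_used,
         n_tested_voxels = sum(x$tested), n_significant_voxels = sum(x$significant)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
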