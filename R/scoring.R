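#' Score one verbal fluency trial from a word list
#'
#' Counts correct, non-repeated words: duplicates (case-insensitive, after
#' whitespace trimming) count once, and only words passing the validity rule
#' are counted. The validity rule is an injectable predicate because
#' language-specific correctness judgments (e.g. which Dutch words count as
#' valid N-words) cannot be encoded generically.
#'
#' @param words Character vector of produced words, in order.
#' @param valid Predicate `function(word) -> logical`; default accepts all.
#' @return Integer count.
#' @export
#' @examples
#' score_fluency_trial(c("ape", "bear", "Ape", "bear")) # 2
score_fluency_trial <- function(words, valid = function(w) TRUE) {
  if (length(words) == 0) return(0L)
  w <- tolower(trimws(as.character(words)))
  w <- unique(w[nzchar(w)])
  sum(vapply(w, function(x) isTRUE(valid(x)), logical(1)))
}

#' Combine the two letter-trial counts into the phonemic fluency score
#'
#' Phonemic fluency is the sum of correct, non-repeated words produced in the
#' N and the A letter trials; it is missing if either trial is missing.
#' Vectorized.
#'
#' @param n_letterN,n_letterA Non-negative counts (may contain `NA`).
#' @return `n_letterN + n_letterA`, `NA` where either is missing.
#' @export
combine_phonemic <- function(n_letterN, n_letterA) {
  ok <- !is.na(n_letterN) & !is.na(n_letterA)
  assert_that(all(n_letterN[!is.na(n_letterN)] >= 0) &&
                all(n_letterA[!is.na(n_letterA)] >= 0),
              "fluency counts must be non-negative")
  out <- n_letterN + n_letterA
  out[!ok] <- NA
  out
}

#' Derive semantic and phonemic fluency scores for a cohort table
#'
#' @param behavior Data frame with columns `animals_2min`, `letterN_1min`,
#'   `letterA_1min` (plus `subject_id` etc.).
#' @return The input tibble with `semantic_raw` (animal count) and
#'   `phonemic_raw` (N + A) appended.
#' @export
fluency_scores <- function(behavior) {
  behavior <- as_tibble(behavior)
  need <- c("animals_2min", "letterN_1min", "letterA_1min")
  miss <- setdiff(need, names(behavior))
  assert_that(length(miss) == 0, "missing fluency columns: %s",
              paste(miss, collapse = ", "))
  behavior |>
    mutate(semantic_raw = .data$animals_2min,
           phonemic_raw = combine_phonemic(.data$letterN_1min, .data$letterA_1min))
}

#' Demographically adjusted z scores
#'
#' Regresses each raw test score on age, sex and education (least squares, on
#' the cohort itself) and standardizes the residual by the residual standard
#' deviation, yielding per-subject z scores that are corrected for
#' demographics. Missing raw scores give missing z (the fit uses the
#' non-missing subjects for that test only). The residual sd uses the
#' regression (n - p) denominator; this choice is recorded in the output
#' metadata (`attr(., "scaling")`).
#'
#' @param data Data frame with `subject_id`, `age`, `sex`, `education` and the
#'   score columns.
#' @param tests Character vector of score column names to adjust.
#' @param education_coding `"linear"` (default: ordinal 1-7 entered as one
#'   linear covariate) or `"categorical"` (factor coding).
#' @param min_n Minimum non-missing subjects required per test (default 5).
#' @return A long tibble with `subject_id`, `test`, `raw`, `z` — one row per
#'   subject x test. Within each test, the non-missing z have mean 0 and unit
#'   root-mean-square on the residual-df scale.
#' @export
adjust_for_demographics <- function(data, tests,
                                    education_coding = c("linear", "categorical"),
                                    min_n = 5) {
  education_coding <- match.arg(education_coding)
  data <- as_tibble(data)
  miss <- setdiff(c("subject_id", "age", "sex", "education", tests), names(data))
  assert_that(length(miss) == 0, "missing columns: %s", paste(miss, collapse = ", "))

  edu <- if (education_coding == "linear") data$education else factor(data$education)
  out <- purrr::map(tests, function(test) {
    raw <- data[[test]]
    ok <- !is.na(raw) & !is.na(data$age) & !is.na(data$sex) & !is.na(edu)
    assert_that(sum(ok) >= min_n, "test '%s': only %d non-missing subjects (need >= %d)",
                test, sum(ok), min_n)
    df <- data.frame(raw = raw[ok], age = data$age[ok], sex = data$sex[ok],
                     education = edu[ok])
    fit <- stats::lm(raw ~ age + sex + education, data = df)
    if (any(is.na(stats::coef(fit)))) {
      # constant or collinear covariates are aliased and dropped by the fit;
      # the adjustment then collapses toward plain standardization
      warn(sprintf("test '%s': aliased demographic covariate(s) dropped: %s",
                   test,
                   paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                         collapse = ", ")))
    }
    sigma <- summary(fit)$sigma
    assert_that(is.finite(sigma) && sigma > 1e-8 * (1 + abs(mean(df$raw))),
                "test '%s': zero residual variance, z scores undefined", test)
    z <- rep(NA_real_, nrow(data))
    z[ok] <- stats::residuals(fit) / sigma
    tibble(subject_id = data$subject_id, test = test, raw = raw, z = z)
  }) |> bind_rows()
  attr(out, "scaling") <- list(residual_sd_denominator = "n - p (residual df)",
                               education_coding = education_coding,
                               reference = "sample (cohort means and sds)")
  out
}

#' Dichotomize test scores against normative cutoffs
#'
#' A score is flagged impaired when it is *strictly below* the cutoff (scores
#' at the normative 5th percentile itself are not impaired).
#'
#' @param scores Long data frame with `subject_id`, `test` and a score column.
#' @param norms Norm table with `test`, `cutoff` (see [read_norm_table()]).
#' @param score_col Which column to compare to the cutoff (default `"raw"`:
#'   the published norms are on the raw-score scale).
#' @return The input with `cutoff_used` and `impaired` (logical, `NA` where
#'   the score is missing) appended; errors if a test lacks a cutoff.
#' @export
dichotomize <- function(scores, norms, score_col = "raw") {
  scores <- as_tibble(scores)
  assert_that(all(c("subject_id", "test", score_col) %in% names(scores)),
              "scores must have subject_id, test and '%s'", score_col)
  missing_tests <- setdiff(unique(scores$test), norms$test)
  assert_that(length(missing_tests) == 0, "no cutoff defined for test(s): %s",
              paste(missing_tests, collapse = ", "))
  scores |>
    left_join(norms |> select("test", cutoff_used = "cutoff"), by = "test") |>
    mutate(impaired = .data[[score_col]] < .data$cutoff_used)
}

#' Summarize impairment prevalence per test
#'
#' @param flags Output of [dichotomize()].
#' @return Tibble per test: `n` (with a defined flag), `n_impaired`,
#'   `percent_impaired` (display percent, integer, half-up rounding).
#' @export
impairment_summary <- function(flags) {
  flags |>
    filter(!is.na(.data$impaired)) |>
    group_by(.data$test) |>
    summarise(n = n(), n_impaired = sum(.data$impaired), .groups = "drop") |>
    mutate(percent_impaired = percent_display(.data$n_impaired, .data$n))
}

#' Pairwise Pearson correlation table
#'
#' Pairwise-complete Pearson correlations with two-tailed p values, the
#' standard way fluency scores are related to the other neuropsychological
#' measures. Pairwise deletion: each pair uses its jointly non-missing
#' subjects, so `n` differs across pairs when tests have different coverage.
#'
#' @param data Data frame holding the measures as columns (e.g. z scores per
#'   test in wide format).
#' @param tests Character vector of column names to correlate.
#' @param min_n Minimum jointly non-missing pairs (default 3).
#' @return Tibble with `test_a`, `test_b`, `r`, `p` (two-tailed), `n`;
#'   includes each unordered pair once (a < b in `tests` order). Constant
#'   series give `NA` with a `note`.
#' @export
correlation_table <- function(data, tests, min_n = 3) {
  data <- as_tibble(data)
  assert_that(all(tests %in% names(data)), "missing measure columns")
  pairs <- utils::combn(tests, 2)
  purrr::map(seq_len(ncol(pairs)), function(idx) {
    a <- pairs[1, idx]; b <- pairs[2, idx]
    ok <- !is.na(data[[a]]) & !is.na(data[[b]])
    n <- sum(ok)
    assert_that(n >= min_n, "pair %s/%s: only %d complete observations", a, b, n)
    if (stats::sd(data[[a]][ok]) == 0 || stats::sd(data[[b]][ok]) == 0) {
      return(tibble(test_a = a, test_b = b, r = NA_real_, p = NA_real_, n = n,
                    note = "constant series"))
    }
    ct <- stats::cor.test(data[[a]][ok], data[[b]][ok], method = "pearson",
                          alternative = "two.sided")
    tibble(test_a = a, test_b = b, r = unname(ct$estimate), p = ct$p.value,
           n = n, note = NA_character_)
  }) |> bind_rows()
}
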