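test_that("trial scoring counts distinct valid words, case- and space-insensitive", {
  expect_equal(score_fluency_trial(character(0)), 0)
  expect_equal(score_fluency_trial(c("ape", "bear", "Ape", "bear")), 2)
  expect_equal(score_fluency_trial(c(" cat", "CAT ", "dog")), 2)

  # enumeration oracle on random word lists with injected duplicates and
  # invalid entries
  set.seed(31)
  vocab <- sprintf("w%02d", 1:30)
  valid_rule <- function(w) !grepl("0", w)   # arbitrary validity predicate
  for (rep in 1:20) {
    words <- sample(vocab, 40, replace = TRUE)
    words[sample(40, 5)] <- toupper(words[sample(40, 5)])
    brute <- length(Filter(valid_rule, unique(tolower(trimws(words)))))
    expect_equal(score_fluency_trial(words, valid_rule), brute)
  }
})

test_that("phonemic combination adds the letter trials and propagates missingness", {
  expect_equal(combine_phonemic(0, 0), 0)
  expect_equal(combine_phonemic(7, 9), 16)
  expect_true(is.na(combine_phonemic(NA, 4)))
  expect_true(is.na(combine_phonemic(4, NA)))
  expect_error(combine_phonemic(-1, 2), "non-negative")

  # per-trial means 7.7 and 8.0 combine to 15.7, displayed as 16 words/2 min
  letterN <- c(rep(8, 7), rep(7, 3)); letterA <- rep(8, 10)  # means 7.7, 8.0
  expect_equal(mean(letterN), 7.7)
  combined <- combine_phonemic(letterN, letterA)
  expect_equal(mean(combined), 15.7)
  expect_equal(round_half_up(mean(combined)), 16)
})

test_that("demographic adjustment standardizes residuals and removes covariate signal", {
  # identical demographics: regression collapses to standardization by the
  # residual-df sd
  d <- make_behavior(sprintf("s%d", 1:8), animals = c(10, 12, 15, 18, 20, 23, 25, 30))
  expect_warning(adj <- adjust_for_demographics(d, "animals_2min"), "aliased")
  raw <- d$animals_2min
  sd_df <- sqrt(sum((raw - mean(raw))^2) / (length(raw) - 1))  # p = 1 (intercept)
  expect_equal(adj$z, (raw - mean(raw)) / sd_df, tolerance = 1e-12)

  # least-squares identities: mean 0, unit rms on the residual-df scale
  set.seed(32)
  d2 <- tibble::tibble(subject_id = sprintf("s%d", 1:60),
                       age = runif(60, 40, 80), sex = rbinom(60, 1, 0.5),
                       education = sample(1:7, 60, TRUE),
                       score = rnorm(60, 20, 5))
  adj2 <- adjust_for_demographics(d2, "score")
  expect_equal(mean(adj2$z), 0, tolerance = 1e-8)
  expect_equal(sum(adj2$z^2) / (60 - 4), 1, tolerance = 1e-8)

  # residual orthogonality: scores driven by age leave z uncorrelated with age
  set.seed(33)
  n <- 500
  d3 <- tibble::tibble(subject_id = sprintf("s%d", 1:n),
                       age = runif(n, 40, 80), sex = rbinom(n, 1, 0.5),
                       education = sample(1:7, n, TRUE))
  d3$score <- 2 * d3$age + rnorm(n)
  adj3 <- adjust_for_demographics(d3, "score")
  expect_lt(abs(cor(adj3$z, d3$age)), 0.05)

  # affine invariance: z unchanged under raw -> a*raw + b, a > 0
  d3$score2 <- 3.7 * d3$score + 11
  adj_both <- adjust_for_demographics(d3, c("score", "score2"))
  z_wide <- tidyr::pivot_wider(adj_both[, c("subject_id", "test", "z")],
                               names_from = "test", values_from = "z")
  expect_equal(z_wide$score, z_wide$score2, tolerance = 1e-10)

  # missing raw gives missing z without dropping the subject elsewhere
  d3$score[5] <- NA
  adj_na <- adjust_for_demographics(d3, "score")
  expect_true(is.na(adj_na$z[5]))
  expect_equal(sum(!is.na(adj_na$z)), n - 1)

  # degenerate designs are rejected with the test named
  d_const <- make_behavior(sprintf("s%d", 1:8), animals = 7)
  expect_error(suppressWarnings(adjust_for_demographics(d_const, "animals_2min")),
               "animals_2min.*zero residual variance")
})

test_that("dichotomization is strict at the cutoff and monotone in the score", {
  norms <- tibble::tibble(test = "semantic", cutoff = 12)
  scores <- tibble::tibble(subject_id = c("a", "b", "c"), test = "semantic",
                           raw = c(12, 12 - 1e-9, 15))
  flags <- dichotomize(scores, norms)
  expect_equal(flags$impaired, c(FALSE, TRUE, FALSE))
  expect_equal(unique(flags$cutoff_used), 12)

  # monotonicity: lowering a score never flips impaired -> not impaired
  set.seed(34)
  s <- tibble::tibble(subject_id = sprintf("s%d", 1:100), test = "semantic",
                      raw = rnorm(100, 15, 4))
  f1 <- dichotomize(s, norms)
  s2 <- s; s2$raw <- s2$raw - abs(rnorm(100))
  f2 <- dichotomize(s2, norms)
  expect_true(all(f2$impaired >= f1$impaired))

  expect_error(dichotomize(s, tibble::tibble(test = "other", cutoff = 1)),
               "no cutoff")

  # drawing from the norm distribution itself impairs ~5% of subjects
  set.seed(35)
  n <- 2000
  draws <- tibble::tibble(subject_id = sprintf("s%d", 1:n), test = "semantic",
                          raw = rnorm(n, 20, 5))
  cut5 <- qnorm(0.05, 20, 5)
  frac <- mean(dichotomize(draws, tibble::tibble(test = "semantic",
                                                 cutoff = cut5))$impaired)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.05) / n
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
})

test_that("correlation table matches the closed-form Pearson oracle and handles missingness pairwise", {
  # exact linear relation
  d <- tibble::tibble(a = 1:10, b = 2 * (1:10) + 3)
  ct <- correlation_table(d, c("a", "b"))
  expect_equal(ct$r, 1)

  # random data vs closed-form r and two-tailed p
  set.seed(36)
  d2 <- tibble::tibble(x = rnorm(40), y = rnorm(40), z = rnorm(40))
  d2$y <- d2$y + 0.4 * d2$x
  ct2 <- correlation_table(d2, c("x", "y", "z"))
  for (i in seq_len(nrow(ct2))) {
    o <- oracle_pearson(d2[[ct2$test_a[i]]], d2[[ct2$test_b[i]]])
    expect_equal(ct2$r[i], o$r, tolerance = 1e-10)
    expect_equal(ct2$p[i], o$p, tolerance = 1e-10)
  }

  # pairwise deletion: ns differ per pair when coverage differs
  d3 <- d2
  d3$y[1:5] <- NA; d3$z[1:12] <- NA
  ct3 <- correlation_table(d3, c("x", "y", "z"))
  get_n <- function(a, b) ct3$n[ct3$test_a == a & ct3$test_b == b]
  expect_equal(get_n("x", "y"), 35)
  expect_equal(get_n("x", "z"), 28)

  # independence null at n = 1000
  set.seed(37)
  d4 <- tibble::tibble(u = rnorm(1000), v = rnorm(1000))
  expect_lt(abs(correlation_table(d4, c("u", "v"))$r), 0.1)

  # constant series reported as missing with a reason
  d5 <- tibble::tibble(u = rnorm(10), k = rep(1, 10))
  ct5 <- correlation_table(d5, c("u", "k"))
  expect_true(is.na(ct5$r))
  expect_equal(ct5$note, "constant series")
})

test_that("impairment summary reproduces prevalence arithmetic", {
  flags <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:93), 2),
    test = rep(c("semantic", "phonemic"), each = 93),
    impaired = c(rep(TRUE, 18), rep(FALSE, 75), rep(TRUE, 29), rep(FALSE, 64))
  )
  s <- impairment_summary(flags)
  expect_equal(s$percent_impaired[s$test == "semantic"], 19)  # 18/93
  expect_equal(s$percent_impaired[s$test == "phonemic"], 31)  # 29/93
})
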