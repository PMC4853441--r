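#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_int map_chr imap
NULL

#' Round half away from zero
#'
#' Display rounding used throughout the reporting tables: halves round up in
#' magnitude (16.5 -> 17, -16.5 -> -17), unlike [base::round()]'s banker's
#' rounding. Percentages in the printed tables use this rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(16.5)   # 17
#' round_half_up(16.666) # 17
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# percent display: count/total -> integer percent (half-up); NA when total == 0
percent_display <- function(count, total) {
  out <- round_half_up(100 * count / total)
  out[rep_len(!(total > 0), length(out))] <- NA_real_
  out
}

stop_fm <- function(msg, ...) abort(sprintf(msg, ...), class = "fluencymap_error")

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_fm(msg, ...)
  invisible(TRUE)
}
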