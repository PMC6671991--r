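# Small shared helpers.

#' Round half away from zero
#'
#' Replication-grade rounding for printed percentages: 0.05 at the last kept
#' digit always rounds up, unlike [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(1.25, 1.15), 1) # 1.3, 1.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic per-record RNG seed derived from (config seed, record index),
# so generation is insertion-order independent. Kept within 32-bit range.
record_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(i) * 7919
  as.integer(s %% 2147483647)
}

pct_of <- function(num, den) 100 * num / den

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "concord7_config_error")
}

is_prob <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
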