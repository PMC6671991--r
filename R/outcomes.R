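# Frequency, rate and trend analyses of consultations and their outcomes.

#' Consultation frequency table
#'
#' Counts consultations by species, agency, work type or region.  Species
#' counting collapses DPS/ESU rows first ([aggregate_dps()]), so a
#' consultation touching several population units of one species counts
#' once for that species; the other keys count distinct consultations.
#'
#' @param records Record tibble.
#' @param key One of `"species"`, `"agency"`, `"work_type"`, `"region"`.
#' @param top Optionally keep only the `top` most frequent levels.
#' @return Tibble `level`, `n`, sorted descending, with attribute `total`.
#' @export
frequency_table <- function(records, key = c("species", "agency",
                                             "work_type", "region"),
                            top = NULL) {
  key <- match.arg(key)
  units <- if (key == "species") {
    aggregate_dps(records)[, c("consultation_id", "species")]
  } else {
    distinct(records[, c("consultation_id", key)])
  }
  out <- units |>
    count(level = .data[[key]], name = "n") |>
    arrange(desc(.data$n), .data$level)
  attr(out, "total") <- sum(out$n)
  if (!is.null(top)) out <- head(out, top)
  out
}

#' Chi-square goodness-of-fit test
#'
#' Tests observed counts against uniform (or supplied) expected frequencies:
#' \eqn{X^2 = \sum (O-E)^2/E} on \eqn{k - 1} degrees of freedom with an
#' upper-tail p-value.
#'
#' @param counts Non-negative integer vector of observed counts.
#' @param expected Optional expected proportions or counts (rescaled to the
#'   observed total); default uniform.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_gof <- function(counts, expected = NULL) {
  if (sum(counts) <= 0) abort("total count must be positive")
  k <- length(counts)
  if (k < 2) abort("need at least two levels")
  p <- if (is.null(expected)) rep(1 / k, k) else expected / sum(expected)
  if (any(p == 0)) abort("expected frequencies must all be positive")
  ct <- suppressWarnings(chisq.test(counts, p = p))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Fit a yearly count trend
#'
#' Fits `count ~ year` by maximum likelihood under either a Poisson
#' log-link GLM or a Gaussian identity-link GLM and reports the per-year
#' slope on the linear-predictor scale.
#'
#' @param series Tibble/data frame with columns `year` and `count`.
#' @param family `"poisson-log"` or `"gaussian-identity"`.
#' @return Tibble: `slope_per_year`, `se`, `statistic`, `p`, `family`,
#'   `converged`.
#' @export
fit_yearly_counts <- function(series, family = c("poisson-log",
                                                 "gaussian-identity")) {
  family <- match.arg(family)
  if (length(unique(series$year)) < 3) {
    abort("need at least 3 distinct years to fit a trend")
  }
  fam <- if (family == "poisson-log") poisson(link = "log") else gaussian()
  fit <- glm(count ~ year, data = series, family = fam)
  sm <- summary(fit)$coefficients
  tibble(
    slope_per_year = sm["year", 1], se = sm["year", 2],
    statistic = sm["year", 3], p = sm["year", 4],
    family = family, converged = fit$converged
  )
}

#' Jeopardy determination rate
#'
#' @param jeopardy Number of jeopardy determinations.
#' @param all Total number of determinations (> 0).
#' @param digits If non-`NULL`, round half-up to this many decimals (the
#'   convention used for printed percentage tables).
#' @return Percentage, raw or rounded.
#' @export
#' @examples
#' jeopardy_rate(60, 3012, digits = 1) # 2.0
jeopardy_rate <- function(jeopardy, all, digits = NULL) {
  if (any(all <= 0)) abort("total determinations must be positive")
  if (any(jeopardy < 0 | jeopardy > all)) {
    abort("jeopardy count must lie in [0, all]")
  }
  out <- pct_of(jeopardy, all)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Summary of consultation outcomes
#'
#' Consultation-level tallies: formal/informal counts, consultations with at
#' least one jeopardy determination, with at least one adverse-modification
#' habitat determination, the disjoint jeopardy-without-AM / AM-without-
#' jeopardy splits, and determination-level jeopardy / AM counts.
#' Percentages are computed against both the formal and the total
#' denominator; when there are no formal consultations the formal-based
#' percentages are `NA` and `formal_denominator_empty` is set.
#'
#' @param records Record tibble (cleaned).
#' @return Named list of counts and percentages.
#' @export
consultation_outcome_summary <- function(records) {
  cons <- records |>
    group_by(.data$consultation_id) |>
    summarise(
      type = .data$type[1],
      any_jeopardy = any(.data$expert_final == "jeopardy"),
      any_am = any(.data$critical_habitat == "adverse modification"),
      .groups = "drop"
    )
  n_total <- nrow(cons)
  n_formal <- sum(cons$type == "formal")
  n_informal <- sum(cons$type == "informal")
  n_jeop <- sum(cons$any_jeopardy)
  n_am <- sum(cons$any_am)
  empty_formal <- n_formal == 0
  pf <- function(x) if (empty_formal) NA_real_ else pct_of(x, n_formal)
  pa <- function(x) if (n_total == 0) NA_real_ else pct_of(x, n_total)
  list(
    n_consultations = n_total,
    n_formal = n_formal,
    n_informal = n_informal,
    formal_pct = pa(n_formal),
    n_jeopardy_consultations = n_jeop,
    jeopardy_pct_of_formal = pf(n_jeop),
    jeopardy_pct_of_all = pa(n_jeop),
    n_adverse_mod_consultations = n_am,
    adverse_mod_pct_of_formal = pf(n_am),
    adverse_mod_pct_of_all = pa(n_am),
    n_jeopardy_without_am = sum(cons$any_jeopardy & !cons$any_am),
    n_am_without_jeopardy = sum(cons$any_am & !cons$any_jeopardy),
    n_jeopardy_determinations = sum(records$expert_final == "jeopardy"),
    n_adverse_mod_determinations =
      sum(records$critical_habitat == "adverse modification"),
    formal_denominator_empty = empty_formal
  )
}

#' Fit the yearly jeopardy-rate trend
#'
#' Fits the proportion of formal consultations ending in jeopardy as a
#' linear function of year with an identity-link, normal-error GLM.
#'
#' @param series Tibble with columns `year`, `jeopardy` (consultations with
#'   a jeopardy finding) and `formal` (formal consultations), all per year.
#' @return Trend tibble as in [fit_yearly_counts()].
#' @export
fit_jeopardy_trend <- function(series) {
  if (length(unique(series$year)) < 3) {
    abort("need at least 3 distinct years to fit a trend")
  }
  if (any(series$formal <= 0)) {
    abort("every year needs at least one formal consultation")
  }
  df <- tibble(year = series$year,
               count = series$jeopardy / series$formal)
  fit <- glm(count ~ year, data = df, family = gaussian())
  sm <- summary(fit)$coefficients
  tibble(
    slope_per_year = sm["year", 1], se = sm["year", 2],
    statistic = sm["year", 3], p = sm["year", 4],
    family = "gaussian-identity", converged = fit$converged
  )
}
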