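# Agency-by-expert concordance: cross-tabulation, ordinal discrepancy
# scoring, weighted Cohen's kappa, and per-agency Kolmogorov-Smirnov
# deviation tests.  The analysis unit throughout is the determination pair,
# not the consultation.

#' Extract scored determination pairs
#'
#' Keeps rows with non-missing agency and expert categories and attaches the
#' ordinal discrepancy score.  The number of excluded rows is carried in the
#' `n_excluded_missing` attribute.
#'
#' @param records Record tibble.
#' @return Tibble of pairs with a `score` column.
#' @export
determination_pairs <- function(records) {
  ok <- records$agency_proposed %in% agency_categories() &
    records$expert_final %in% expert_categories()
  out <- records[ok, , drop = FALSE]
  out$score <- discrepancy_score(out$agency_proposed, out$expert_final)
  attr(out, "n_excluded_missing") <- sum(!ok)
  out
}

#' Build the agency-by-expert concordance table
#'
#' Cross-tabulates expert final determinations (rows) against agency
#' proposed determinations (columns).  Pairs with a missing category are
#' excluded and counted in the `n_excluded` attribute.  The empty input
#' yields a valid all-zero table.
#'
#' @param pairs Tibble with `agency_proposed` and `expert_final` columns
#'   (e.g. from [determination_pairs()] or [generate_consultations()]).
#' @return A `concordance_table`: 4x5 integer count matrix with attributes
#'   `N` (grand total) and `n_excluded`.
#' @export
build_concordance_table <- function(pairs) {
  ok <- pairs$agency_proposed %in% agency_categories() &
    pairs$expert_final %in% expert_categories()
  tab <- table(
    factor(pairs$expert_final[ok], levels = expert_categories()),
    factor(pairs$agency_proposed[ok], levels = agency_categories())
  )
  m <- matrix(as.integer(tab), nrow = 4,
              dimnames = list(expert = expert_categories(),
                              agency = agency_categories()))
  new_concordance_table(m, n_excluded = sum(!ok))
}

new_concordance_table <- function(counts, n_excluded = 0L) {
  stopifnot(is.matrix(counts), all(dim(counts) == c(4, 5)), all(counts >= 0))
  structure(counts, N = sum(counts), n_excluded = as.integer(n_excluded),
            class = c("concordance_table", "matrix"))
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Agency-by-expert concordance table (N =", attr(x, "N"), ")\n")
  m <- unclass(x)
  attributes(m)[c("N", "n_excluded")] <- NULL
  with_margins <- rbind(cbind(m, total = rowSums(m)),
                        total = c(colSums(m), sum(m)))
  print(with_margins, ...)
  invisible(x)
}

#' Write a concordance table (with margins) to CSV
#'
#' @param table A `concordance_table`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_concordance_table <- function(table, path) {
  m <- unclass(table)
  df <- as.data.frame(cbind(m, total = rowSums(m)))
  df <- rbind(df, total = c(colSums(m), sum(m)))
  df <- cbind(expert = rownames(df), df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' Weighted Cohen's kappa from a concordance table
#'
#' Computes the disagreement-weighted kappa
#' \deqn{K_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij} / N}
#'                   {\sum_{ij} w_{ij} r_i c_j / N^2}}
#' where \eqn{O} is the observed count matrix, \eqn{r, c} its margins and
#' \eqn{w} a disagreement weight matrix with 0 on agreement cells.
#' \eqn{K_w = 1} at perfect agreement and 0 when the table exactly matches
#' independence of its margins.
#'
#' @param table A `concordance_table` (or plain 4x5 count matrix).
#' @param weights Weight matrix aligned with [score_matrix()]; defaults to
#'   0.25 per ordinal discrepancy step.
#' @return A `kappa_result` list: `kappa`, `observed` and `expected`
#'   weighted disagreement, and `N`.
#' @export
weighted_kappa <- function(table, weights = default_weight_matrix()) {
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == dim(weights)))
  N <- sum(m)
  if (N == 0) abort("cannot compute kappa for an empty table")
  r <- rowSums(m); cl <- colSums(m)
  observed <- sum(weights * m) / N
  expected <- sum(weights * outer(r, cl)) / N^2
  if (expected == 0) {
    abort("kappa undefined: expected weighted disagreement is zero (degenerate margins)",
          class = "concord7_degenerate_kappa")
  }
  structure(list(kappa = 1 - observed / expected, observed = observed,
                 expected = expected, N = N),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted kappa: %.4f (observed %.4f / expected %.4f, N = %d)\n",
              x$kappa, x$observed, x$expected, x$N))
  invisible(x)
}

#' Per-agency discrepancy-score distributions
#'
#' Empirical distribution of discrepancy scores over \{-3..3\} for each
#' agency, with counts and percentages (summing to 100 within each agency).
#'
#' @param pairs Scored pairs from [determination_pairs()].
#' @return Tibble with columns `agency`, `score`, `n`, `pct`, `n_agency`.
#' @export
score_distribution <- function(pairs) {
  pairs |>
    count(.data$agency, score = factor(.data$score, levels = -3:3),
          .drop = FALSE) |>
    group_by(.data$agency) |>
    mutate(n_agency = sum(.data$n),
           pct = 100 * .data$n / .data$n_agency) |>
    ungroup() |>
    mutate(score = as.integer(as.character(.data$score))) |>
    filter(.data$n_agency > 0)
}

#' Share of disagreements that are underestimates
#'
#' Among non-zero discrepancy scores, the fraction that are negative
#' (agency underestimated effects relative to the expert finding).
#'
#' @param scores Integer vector of discrepancy scores.
#' @return Fraction in \[0, 1\].
#' @export
underestimation_share <- function(scores) {
  nz <- scores[scores != 0]
  if (length(nz) == 0) {
    abort("underestimation share undefined: no disagreements",
          class = "concord7_no_disagreement")
  }
  sum(nz < 0) / length(nz)
}

#' Two-sample KS test of one agency's score distribution
#'
#' Compares an agency's discrepancy scores against the pooled reference
#' distribution with a two-tailed two-sample Kolmogorov-Smirnov test
#' (D = sup distance between the empirical step CDFs; asymptotic p-value).
#' Agencies with fewer than `min_n` scores are returned as skipped rather
#' than tested.
#'
#' @param scores Integer scores for the focal agency.
#' @param reference Pooled scores (by default including the focal agency's;
#'   see [ks_by_agency()] for the leave-one-out variant).
#' @param min_n Minimum number of scores required to test.
#' @return One-row tibble: `n`, `D`, `p`, `skipped`.
#' @export
ks_agency_test <- function(scores, reference, min_n = 20) {
  if (length(reference) == 0) abort("empty reference distribution")
  if (length(scores) < min_n) {
    return(tibble(n = length(scores), D = NA_real_, p = NA_real_,
                  skipped = TRUE))
  }
  ks <- suppressWarnings(ks.test(scores, reference, exact = FALSE))
  tibble(n = length(scores), D = unname(ks$statistic),
         p = unname(ks$p.value), skipped = FALSE)
}

#' KS deviation tests for every agency
#'
#' @param pairs Scored pairs from [determination_pairs()].
#' @param min_n Minimum scores per agency (default 20).
#' @param leave_one_out If `TRUE`, the focal agency's scores are removed
#'   from the pooled reference; the default keeps them in (the pooled
#'   distribution "among all agencies").
#' @return Tibble with one row per agency: `agency`, `n`, `D`, `p`,
#'   `skipped`, `significant` (p < 0.05).
#' @export
ks_by_agency <- function(pairs, min_n = 20, leave_one_out = FALSE) {
  agencies <- sort(unique(pairs$agency))
  rows <- lapply(agencies, function(a) {
    sc <- pairs$score[pairs$agency == a]
    ref <- if (leave_one_out) pairs$score[pairs$agency != a] else pairs$score
    res <- ks_agency_test(sc, ref, min_n = min_n)
    res$agency <- a
    res
  })
  out <- bind_rows(rows)[, c("agency", "n", "D", "p", "skipped")]
  out$significant <- !out$skipped & out$p < 0.05
  out
}
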