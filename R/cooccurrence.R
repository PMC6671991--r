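# Pairwise co-jeopardization analysis on a binary species-by-consultation
# matrix, under the analytic fixed-margin (hypergeometric) null.

#' Build the binary species-by-consultation jeopardy matrix
#'
#' Rows are species with at least one jeopardy determination (DPS/ESUs
#' aggregated to species); columns are consultations.  A cell is 1 when the
#' species received a jeopardy determination in that consultation.
#'
#' @param records Record tibble.
#' @param universe Column universe: `"jeopardy"` (consultations with at
#'   least one jeopardy determination, the default) or `"formal"` (all
#'   formal consultations).
#' @return Binary integer matrix, or an empty 0x0 matrix if no jeopardy
#'   determination exists.
#' @export
build_binary_matrix <- function(records, universe = c("jeopardy", "formal")) {
  universe <- match.arg(universe)
  sp <- aggregate_dps(records)
  jeop <- sp[sp$any_jeopardy, , drop = FALSE]
  if (nrow(jeop) == 0) {
    return(matrix(integer(0), 0, 0,
                  dimnames = list(species = NULL, consultation = NULL)))
  }
  cons <- if (universe == "jeopardy") {
    sort(unique(jeop$consultation_id))
  } else {
    sort(unique(records$consultation_id[records$type == "formal"]))
  }
  species <- sort(unique(jeop$species))
  m <- matrix(0L, length(species), length(cons),
              dimnames = list(species = species, consultation = cons))
  idx <- cbind(match(jeop$species, species),
               match(jeop$consultation_id, cons))
  idx <- idx[!is.na(idx[, 2]), , drop = FALSE]
  m[idx] <- 1L
  m
}

#' Hypergeometric co-jeopardization test for one species pair
#'
#' Under the fixed-margin null, the number of consultations jeopardizing
#' both species follows the hypergeometric distribution
#' \eqn{P(j) = \binom{N_1}{j}\binom{N-N_1}{N_2-j} / \binom{N}{N_2}}.
#' Reports the expected co-jeopardization count \eqn{N_1 N_2 / N}, the
#' effect size (observed - expected), tail probabilities
#' \eqn{p_{gt} = P(j \ge obs)}, \eqn{p_{lt} = P(j \le obs)}, and the
#' observed pair probability under several denominators (per consultation,
#' per species, per union) since conventions differ between reports.
#'
#' @param N Number of consultations (columns of the binary matrix).
#' @param N1,N2 Per-species jeopardy consultation counts.
#' @param observed Observed co-jeopardization count.
#' @return One-row tibble of the quantities above.
#' @export
#' @examples
#' cooccur_test(N = 4, N1 = 2, N2 = 2, observed = 2) # p_gt = 1/6
cooccur_test <- function(N, N1, N2, observed) {
  if (N1 < 0 || N2 < 0 || N1 > N || N2 > N) {
    abort("need 0 <= N1, N2 <= N")
  }
  lo <- max(0, N1 + N2 - N)
  if (observed < lo || observed > min(N1, N2)) {
    abort("observed co-jeopardization count incompatible with margins")
  }
  expected <- if (N > 0) N1 * N2 / N else 0
  p_gt <- phyper(observed - 1, N1, N - N1, N2, lower.tail = FALSE)
  p_lt <- phyper(observed, N1, N - N1, N2)
  uni <- N1 + N2 - observed
  tibble(
    N = N, N1 = N1, N2 = N2, observed = observed,
    expected = expected, effect = observed - expected,
    p_gt = p_gt, p_lt = p_lt,
    prob_obs = if (N > 0) observed / N else 0,
    prob_obs_n1 = if (N1 > 0) observed / N1 else NA_real_,
    prob_obs_n2 = if (N2 > 0) observed / N2 else NA_real_,
    prob_obs_union = if (uni > 0) observed / uni else NA_real_
  )
}

#' Co-jeopardization tests for all species pairs
#'
#' Runs [cooccur_test()] on every unordered pair of rows of the binary
#' matrix.  Row order does not affect results.  The pair with the maximum
#' observed pair probability (`prob_obs`) is carried in the `max_pair`
#' attribute.
#'
#' @param matrix Binary matrix from [build_binary_matrix()].
#' @param min_n Pairs where either species has fewer than `min_n` jeopardy
#'   consultations are flagged `low_support` (still reported).
#' @return Tibble with one row per pair: `species_a`, `species_b` (sorted
#'   within pair), test columns from [cooccur_test()], `significant`
#'   (p_gt < 0.05) and `low_support`.
#' @export
all_pairs <- function(matrix, min_n = 1) {
  if (nrow(matrix) < 2) abort("need at least two species rows")
  species <- rownames(matrix)
  N <- ncol(matrix)
  rs <- rowSums(matrix)
  combos <- utils::combn(order(species), 2)
  rows <- lapply(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    res <- cooccur_test(N, rs[i], rs[j],
                        sum(matrix[i, ] == 1L & matrix[j, ] == 1L))
    res$species_a <- species[i]
    res$species_b <- species[j]
    res
  })
  out <- bind_rows(rows)
  out <- out[, c("species_a", "species_b", setdiff(names(out),
                                                   c("species_a", "species_b")))]
  out$significant <- out$p_gt < 0.05
  out$low_support <- out$N1 < min_n | out$N2 < min_n
  best <- which.max(out$prob_obs)
  attr(out, "max_pair") <- out[best, c("species_a", "species_b", "prob_obs")]
  out
}
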