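# Fixed-margin permutation test for disproportionate jeopardy frequency
# across species-by-work-type combinations.

#' Build the species-by-work-type jeopardy count matrix
#'
#' Cell (s, w) counts jeopardy determinations for species s (DPS/ESUs
#' aggregated to the species) under work type w.
#'
#' @param records Record tibble.
#' @return Integer count matrix (species x work type), or an empty 0x0
#'   matrix when no jeopardy determinations exist.
#' @export
build_jeopardy_matrix <- function(records) {
  jeop <- records[records$expert_final == "jeopardy", , drop = FALSE]
  if (nrow(jeop) == 0) {
    return(matrix(integer(0), 0, 0,
                  dimnames = list(species = NULL, work_type = NULL)))
  }
  tab <- table(jeop$species, jeop$work_type)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(species = rownames(tab),
                              work_type = colnames(tab)))
  m
}

#' Draw one fixed-margin randomisation of a count matrix
#'
#' Samples a non-negative integer matrix with exactly the row sums, column
#' sums and grand total of `matrix`, from the conditional (multivariate
#' hypergeometric / Patefield) distribution of tables given margins.
#'
#' @param matrix Non-negative integer count matrix.
#' @return A matrix with identical margins.
#' @export
sample_fixed_margins <- function(matrix) {
  r <- rowSums(matrix); cl <- colSums(matrix)
  if (sum(r) == 0) abort("degenerate matrix: all margins zero")
  # a single row or column is forced by its margins
  if (nrow(matrix) == 1 || ncol(matrix) == 1) return(matrix)
  out <- r2dtable(1, r, cl)[[1]]
  dimnames(out) <- dimnames(matrix)
  out
}

#' Fixed-margin permutation enrichment test
#'
#' For every cell of the jeopardy count matrix, compares the observed count
#' with `n_perm` fixed-margin randomisations.  Reports the effect size
#' (observed minus mean simulated count), the standard deviation of
#' simulated counts, and upper/lower tail probabilities.  Rows and columns
#' with a zero margin carry no information under the fixed-margin null and
#' are dropped before permutation (listed in the `dropped` attribute).
#'
#' Two p-value conventions are available: `"greater"` is the plain
#' proportion of permutations whose simulated count exceeds (`p_gt`) or
#' falls below (`p_lt`) the observed count; `"smoothed"` is the
#' add-one-smoothed version \eqn{(\#\{sim \ge obs\} + 1)/(n_{perm} + 1)}
#' (and its mirror), which never returns 0 and is conservative for sparse
#' cells.
#'
#' @param matrix Count matrix from [build_jeopardy_matrix()].
#' @param n_perm Number of fixed-margin randomisations (default 1000).
#' @param seed Integer seed for the randomisations.
#' @param convention `"greater"` (plain proportion) or `"smoothed"`.
#' @return Long tibble: `species`, `work_type`, `observed`, `effect`, `sd`,
#'   `p_gt`, `p_lt`, `significant` (p_gt < 0.05) and a supplementary
#'   Benjamini-Hochberg column `p_gt_bh` (not part of the core procedure).
#' @export
permutation_enrichment <- function(matrix, n_perm = 1000, seed = NULL,
                                   convention = c("greater", "smoothed")) {
  convention <- match.arg(convention)
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (length(matrix) == 0 || sum(matrix) == 0) {
    abort("degenerate matrix: no jeopardy determinations to permute")
  }
  r <- rowSums(matrix); cl <- colSums(matrix)
  dropped <- list(species = rownames(matrix)[r == 0],
                  work_type = colnames(matrix)[cl == 0])
  m <- matrix[r > 0, cl > 0, drop = FALSE]
  r <- rowSums(m); cl <- colSums(m)

  if (!is.null(seed)) set.seed(seed)
  sims <- if (nrow(m) == 1 || ncol(m) == 1) {
    rep(list(unclass(m)), n_perm)   # margins force the table
  } else {
    r2dtable(n_perm, r, cl)
  }
  sim_arr <- array(unlist(sims), dim = c(nrow(m), ncol(m), n_perm))

  mean_sim <- apply(sim_arr, c(1, 2), mean)
  sd_sim <- apply(sim_arr, c(1, 2), sd)
  if (n_perm == 1) sd_sim[] <- 0
  gt <- apply(sweep(sim_arr, c(1, 2), m, FUN = function(s, o) s > o),
              c(1, 2), sum)
  ge <- apply(sweep(sim_arr, c(1, 2), m, FUN = function(s, o) s >= o),
              c(1, 2), sum)
  lt <- apply(sweep(sim_arr, c(1, 2), m, FUN = function(s, o) s < o),
              c(1, 2), sum)
  le <- apply(sweep(sim_arr, c(1, 2), m, FUN = function(s, o) s <= o),
              c(1, 2), sum)
  if (convention == "greater") {
    p_gt <- gt / n_perm
    p_lt <- lt / n_perm
  } else {
    p_gt <- (ge + 1) / (n_perm + 1)
    p_lt <- (le + 1) / (n_perm + 1)
  }

  out <- tibble(
    species = rep(rownames(m), times = ncol(m)),
    work_type = rep(colnames(m), each = nrow(m)),
    observed = as.integer(m),
    effect = as.vector(m - mean_sim),
    sd = as.vector(sd_sim),
    p_gt = as.vector(p_gt),
    p_lt = as.vector(p_lt)
  )
  out$significant <- out$p_gt < 0.05
  out$p_gt_bh <- stats::p.adjust(out$p_gt, method = "BH")
  attr(out, "dropped") <- dropped
  attr(out, "n_perm") <- n_perm
  attr(out, "convention") <- convention
  out
}
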