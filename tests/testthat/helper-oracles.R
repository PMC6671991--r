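# Independent brute-force oracles used to check the analytic routines, plus
# the fixed study configurations for the simulation-based property tests.
# The oracles deliberately avoid the code paths they validate.

# sup distance between the empirical CDFs of two integer samples
ks_D_oracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), 0)
  Fy <- vapply(grid, function(g) mean(y <= g), 0)
  max(abs(Fx - Fy))
}

# direct evaluation of the goodness-of-fit statistic
chisq_oracle <- function(counts, p = NULL) {
  if (is.null(p)) p <- rep(1 / length(counts), length(counts))
  e <- sum(counts) * p
  sum((counts - e)^2 / e)
}

# least-squares slope from the normal equations
ls_slope_oracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# exhaustive distribution of the co-occurrence count: species 1 occupies
# columns 1..N1; enumerate every placement of species 2 over N columns and
# tabulate the overlap.  Returns P(j) for j = 0..min(N1, N2).
hyper_overlap_oracle <- function(N, N1, N2) {
  js <- 0:min(N1, N2)
  probs <- rep(0, length(js))
  if (N2 == 0 || N == 0) {
    probs[1] <- 1
  } else {
    placements <- utils::combn(N, N2)
    overlaps <- colSums(placements <= N1)
    tab <- tabulate(overlaps + 1L, nbins = length(js))
    probs <- tab / ncol(placements)
  }
  stats::setNames(probs, js)
}

# exhaustive fixed-margin table distribution for 2-row matrices: enumerate
# every feasible top row a (bottom row is then forced) and weight it by the
# multivariate hypergeometric mass choose(c_j, a_j) / choose(N, r1).
enum_two_row_tables <- function(r, cl) {
  stopifnot(length(r) == 2)
  k <- length(cl)
  N <- sum(r)
  grid <- expand.grid(lapply(cl, function(c_j) 0:c_j))
  keep <- rowSums(grid) == r[1]
  grid <- grid[keep, , drop = FALSE]
  mass <- apply(grid, 1, function(a) prod(choose(cl, a))) / choose(N, r[1])
  list(top_rows = as.matrix(grid), prob = mass)
}

# all multisets of a given size over a support, as a list of sorted vectors
all_multisets <- function(support, size) {
  if (size == 0) return(list(integer(0)))
  idx <- utils::combn(length(support) + size - 1, size)
  lapply(seq_len(ncol(idx)), function(j) {
    support[idx[, j] - seq_len(size) + 1]
  })
}

# ---- fixed study configurations for simulation properties -----------------

# focused pool used for the enrichment power / null-calibration studies:
# 6 species without DPS splits, 5 uniform work types, unbiased agencies,
# 30% formal consultations, 4% jeopardy within the formal category draw.
focused_config <- function(seed, n = 2000, enrich_multiplier = NULL,
                           cojeopardy = FALSE, bias = 0, noise = 0.2) {
  enr <- if (is.null(enrich_multiplier)) {
    tibble::tibble(species = character(), work_type = character(),
                   multiplier = numeric())
  } else {
    tibble::tibble(species = "Species A", work_type = "work1",
                   multiplier = enrich_multiplier)
  }
  synthetic_config(
    n_consultations = n,
    species_pool = tibble::tibble(
      species = paste("Species", LETTERS[1:6]),
      dps = replicate(6, character(0), simplify = FALSE)
    ),
    agency_pool = tibble::tibble(
      agency = c("Agency One", "Agency Two"),
      weight = c(1, 1), bias = c(bias, bias)
    ),
    worktype_pool = tibble::tibble(work_type = paste0("work", 1:5),
                                   weight = rep(1, 5)),
    region_pool = tibble::tibble(region = "West Coast", weight = 1),
    p_formal = 0.3,
    base_determination_probs = c("no effect" = 0.10, "NLAA" = 0.60,
                                 "no jeopardy" = 0.26, "jeopardy" = 0.04),
    noise = noise,
    p_proposed_jeopardy = 0,
    species_mean = if (cojeopardy) 3 else 2, species_max = 6,
    p_extra_dps = 0,
    p_date_error = 0,
    jeopardy_enrichment = enr,
    cojeopardy_groups = if (cojeopardy) {
      list(c("Species A", "Species B"))
    } else {
      list()
    },
    cojeopardy_shock_prob = 0.2,
    cojeopardy_multiplier = 1000,
    seed = seed
  )
}

perfect_agreement_config <- function(seed, n = 500) {
  cfg <- focused_config(seed, n = n, noise = 0)
  cfg
}
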