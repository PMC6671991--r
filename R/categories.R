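# Determination category enumerations shared by all modules.
#
# Expert (final) determinations are one of four categories; action-agency
# proposals span five because an agency may propose LAA, which the expert
# agency must resolve into a jeopardy / no jeopardy finding, or (rarely)
# propose a jeopardy outcome directly.

#' Determination category sets
#'
#' Canonical category labels used throughout the package.
#' `expert_categories()` are the four possible final determinations by the
#' expert wildlife agency; `agency_categories()` are the five possible
#' action-agency proposals; `critical_habitat_categories()` cover critical
#' habitat determinations, including the "no critical habitat" code used for
#' species without designated habitat at consultation time.
#'
#' @return Character vector of category labels, in ordinal severity order.
#' @export
expert_categories <- function() {
  c("no effect", "NLAA", "no jeopardy", "jeopardy")
}

#' @rdname expert_categories
#' @export
agency_categories <- function() {
  c("no effect", "NLAA", "LAA", "proposed no jeopardy", "proposed jeopardy")
}

#' @rdname expert_categories
#' @export
critical_habitat_categories <- function() {
  c("no effect", "NLAA", "no adverse modification", "adverse modification",
    "no critical habitat")
}

consultation_types <- function() c("formal", "informal", "combined")
consultation_complexities <- function() {
  c("standard", "programmatic", "conference", "early")
}
all_regions <- function() {
  c("Northeast", "Southeast", "Alaska", "Pacific Island", "West Coast",
    "Southwest", "Northwest")
}

#' Ordinal discrepancy score matrix
#'
#' The 4x5 matrix of ordinal discrepancy scores for every (expert final,
#' agency proposed) determination combination.  Positive scores mean the
#' agency overestimated effects relative to the expert determination,
#' negative scores mean it underestimated them, and 0 marks agreement.
#' Agreement includes an agency LAA proposal resolved by the expert into
#' either jeopardy or no jeopardy, and the rare direct jeopardy-range
#' proposals that match the final finding.
#'
#' @return Integer matrix with expert categories as rows and agency
#'   categories as columns; entries lie in -3..3.
#' @seealso [discrepancy_score()], [default_weight_matrix()]
#' @export
score_matrix <- function() {
  m <- matrix(
    c( 0L,  1L,  2L,  2L,  3L,
      -1L,  0L,  1L,  1L,  2L,
      -2L, -1L,  0L,  0L,  1L,
      -3L, -2L,  0L, -1L,  0L),
    nrow = 4, byrow = TRUE,
    dimnames = list(expert = expert_categories(), agency = agency_categories())
  )
  m
}

#' Score a pair of determinations
#'
#' Vectorised lookup into [score_matrix()].
#'
#' @param agency Character vector of agency-proposed categories.
#' @param expert Character vector of expert final categories.
#' @return Integer vector of discrepancy scores in -3..3.
#' @export
#' @examples
#' discrepancy_score("NLAA", "no effect")   # +1
#' discrepancy_score("no effect", "jeopardy") # -3
discrepancy_score <- function(agency, expert) {
  sm <- score_matrix()
  i <- match(expert, rownames(sm))
  j <- match(agency, colnames(sm))
  bad <- is.na(i) | is.na(j)
  if (any(bad)) {
    abort(sprintf(
      "cannot score pairs with missing or unknown categories: %s",
      paste(unique(paste0("(", agency[bad], ", ", expert[bad], ")")),
            collapse = ", ")))
  }
  sm[cbind(i, j)]
}

#' Default disagreement weight matrix
#'
#' Disagreement weights for the weighted kappa statistic: each ordinal step
#' of discrepancy adds 0.25, so weights take values in
#' \{0, 0.25, 0.5, 0.75, 1\} with agreement cells at 0.
#'
#' @param per_step Weight added per unit of absolute discrepancy score.
#' @return Numeric 4x5 matrix aligned with [score_matrix()].
#' @export
default_weight_matrix <- function(per_step = 0.25) {
  w <- abs(score_matrix()) * per_step
  storage.mode(w) <- "double"
  w
}
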