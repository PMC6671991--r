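# Published reference values from the national NMFS section 7 consultation
# record (2000 - mid-2017), used as worked examples and replication
# fixtures.  These are inputs (printed tables), not computed results.

#' Reference agency-by-expert concordance table
#'
#' The published 4x5 cross-tabulation of agency-proposed vs expert final
#' determinations over all recorded consultations, 2000 to mid-2017
#' (91,435 determination pairs).
#'
#' @return A `concordance_table`.
#' @export
reference_concordance_table <- function() {
  counts <- matrix(
    c(3671L,  7215L,  1377L,  6L, 3L,
       853L, 59258L,  2509L,  5L, 0L,
       163L,  2246L, 13454L, 17L, 0L,
        55L,   164L,   439L,  0L, 0L),
    nrow = 4, byrow = TRUE,
    dimnames = list(expert = expert_categories(), agency = agency_categories())
  )
  new_concordance_table(counts)
}

#' Reference jeopardy-rate table for the ten most-jeopardized species
#'
#' Published counts of jeopardy determinations and all determinations for
#' the ten species with the most jeopardy determinations, with the printed
#' one-decimal percentage.
#'
#' @return Tibble: `species`, `n_dps_jeopardized`, `n_dps_total`,
#'   `jeopardy_determinations`, `all_determinations`, `printed_pct`.
#' @export
reference_jeopardy_species <- function() {
  tibble(
    species = c("Green sea turtle", "Kemp's ridley sea turtle", "Killer whale",
                "Loggerhead sea turtle", "North Atlantic right whale",
                "Leatherback sea turtle", "Chum salmon", "Sockeye salmon",
                "Coho salmon", "Steelhead"),
    n_dps_jeopardized = c(1L, NA, 1L, 2L, NA, NA, 2L, 2L, 5L, 13L),
    n_dps_total = c(5L, NA, 1L, 8L, NA, NA, 4L, 7L, 7L, 15L),
    jeopardy_determinations = c(9L, 9L, 9L, 10L, 10L, 11L, 16L, 24L, 31L, 60L),
    all_determinations = c(778L, 614L, 186L, 768L, 176L, 703L, 564L, 675L,
                           1490L, 3012L),
    printed_pct = c(1.2, 1.5, 4.8, 1.3, 5.7, 1.6, 2.8, 3.6, 2.1, 2.0)
  )
}

#' Reference consultation outcome counts
#'
#' Published headline counts: informal/formal consultations, consultations
#' with jeopardy or adverse-modification findings, determination-level
#' jeopardy/adverse-modification counts, and the separately reported
#' overall total (which exceeds the informal+formal sum; both are kept,
#' unreconciled).
#'
#' @return Named list of integers.
#' @export
reference_outcome_counts <- function() {
  list(
    informal = 19826L, formal = 4934L,
    jeopardy_consultations = 72L,
    adverse_mod_consultations = 55L,
    jeopardy_determinations = 641L,
    adverse_mod_determinations = 503L,
    jeopardy_without_am = 37L,
    am_without_jeopardy = 3L,
    reported_total = 24893L
  )
}

#' Replicate the published summary tables
#'
#' Recomputes, from the published counts, the derived quantities each table
#' prints, and compares them cell by cell.
#'
#' * `"concordance"` — rebuilds the concordance table from an expanded
#'   pair set and checks every cell plus the grand total; also reports the
#'   weighted kappa under the package's default weights and the zero-score
#'   (agreement) and negative-score shares in both table orientations.
#' * `"jeopardy_species"` — recomputes each species' jeopardy percentage
#'   (half-up, one decimal) against the printed value.
#' * `"outcome_summary"` — recomputes the formal share and the jeopardy /
#'   adverse-modification percentages of formal and of all consultations.
#'
#' @param mode One of `"concordance"`, `"jeopardy_species"`,
#'   `"outcome_summary"`.
#' @return A tibble with columns `quantity`, `computed`, `printed`, `pass`
#'   (printed is `NA` where nothing was printed to compare against).
#' @export
replicate_reference_tables <- function(mode = c("concordance",
                                                "jeopardy_species",
                                                "outcome_summary")) {
  mode <- match.arg(mode)
  if (mode == "jeopardy_species") {
    ref <- reference_jeopardy_species()
    return(tibble(
      quantity = paste0(ref$species, "_pct"),
      computed = jeopardy_rate(ref$jeopardy_determinations,
                               ref$all_determinations, digits = 1),
      printed = ref$printed_pct
    ) |> mutate(pass = .data$computed == .data$printed))
  }
  if (mode == "outcome_summary") {
    oc <- reference_outcome_counts()
    total <- oc$informal + oc$formal
    comp <- c(
      formal_share_pct = round_half_up(pct_of(oc$formal, total), 1),
      jeopardy_pct_of_formal =
        round_half_up(pct_of(oc$jeopardy_consultations, oc$formal), 1),
      jeopardy_pct_of_all =
        round_half_up(pct_of(oc$jeopardy_consultations, total), 1),
      adverse_mod_pct_of_formal =
        round_half_up(pct_of(oc$adverse_mod_consultations, oc$formal), 1),
      adverse_mod_pct_of_all =
        round_half_up(pct_of(oc$adverse_mod_consultations, total), 1),
      informal_plus_formal = total,
      reported_total = oc$reported_total
    )
    printed <- c(19.9, 1.5, 0.3, 1.1, 0.2, NA, 24893)
    return(tibble(quantity = names(comp), computed = unname(comp),
                  printed = printed) |>
             mutate(pass = is.na(.data$printed) |
                      .data$computed == .data$printed))
  }
  # concordance: expand the printed table to pairs, rebuild, compare
  ref <- reference_concordance_table()
  pairs <- tibble(
    expert_final = rep(rep(rownames(ref), times = ncol(ref)), as.integer(ref)),
    agency_proposed = rep(rep(colnames(ref), each = nrow(ref)), as.integer(ref))
  )
  rebuilt <- build_concordance_table(pairs)
  kap <- weighted_kappa(ref)
  sm <- score_matrix()
  n_zero <- sum(unclass(ref)[sm == 0])
  n_neg <- sum(unclass(ref)[sm < 0])
  n_pos <- sum(unclass(ref)[sm > 0])
  cells <- tibble(
    quantity = paste0("cell_", gsub(" ", "_", rep(rownames(ref), ncol(ref))),
                      "__", gsub(" ", "_", rep(colnames(ref), each = nrow(ref)))),
    computed = as.numeric(rebuilt),
    printed = as.numeric(ref)
  )
  extras <- tibble(
    quantity = c("grand_total", "weighted_kappa_default_weights",
                 "agreement_share_pct", "negative_score_share_of_disagreements_pct",
                 "positive_score_share_of_disagreements_pct"),
    computed = c(attr(rebuilt, "N"), kap$kappa,
                 pct_of(n_zero, attr(ref, "N")),
                 pct_of(n_neg, n_neg + n_pos),
                 pct_of(n_pos, n_neg + n_pos)),
    printed = c(91435, NA, NA, NA, NA)
  )
  bind_rows(cells, extras) |>
    mutate(pass = is.na(.data$printed) | .data$computed == .data$printed)
}
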