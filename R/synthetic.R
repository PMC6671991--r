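# Synthetic consultation-record generator.
#
# Generates consultation records with the statistical structure the analysis
# pipeline assumes: a species pool in which some species carry multiple
# DPS/ESU units, skewed agency and work-type frequencies, a latent
# expert-determination process with per-agency ordinal over/under-estimation
# bias, rare jeopardy outcomes concentrated in formal consultations,
# optional planted species-by-work-type jeopardy enrichment, and optional
# correlated multi-species jeopardy within single consultations.

default_species_pool <- function() {
  tibble(
    species = c("Chinook salmon", "Steelhead", "Coho salmon", "Sockeye salmon",
                "Chum salmon", "Green sturgeon", "Killer whale",
                "Leatherback sea turtle", "Green sea turtle",
                "North Atlantic right whale", "Eulachon"),
    dps = list(
      c("Puget Sound ESU", "Sacramento River winter-run ESU",
        "Snake River fall-run ESU"),
      c("California Central Valley DPS", "Lower Columbia River DPS",
        "Snake River Basin DPS", "Puget Sound DPS"),
      c("Central California Coast ESU", "Lower Columbia River ESU",
        "Oregon Coast ESU"),
      c("Snake River ESU", "Ozette Lake ESU"),
      c("Hood Canal summer-run ESU", "Columbia River ESU"),
      "Southern DPS",
      "Southern Resident DPS",
      character(0),
      c("East Pacific DPS", "North Atlantic DPS"),
      character(0),
      "Southern DPS"
    )
  )
}

default_agency_pool <- function() {
  tibble(
    agency = c("Army Corps of Engineers", "Forest Service", "NMFS",
               "Federal Emergency Management Agency",
               "Environmental Protection Agency", "Bureau of Land Management",
               "National Park Service", "Federal Energy Regulatory Commission",
               "Coast Guard", "Bureau of Indian Affairs"),
    weight = c(6, 1, 1.5, 0.8, 0.4, 0.5, 0.3, 0.4, 0.4, 0.2),
    bias = c(0.3, -0.2, -0.1, -0.05, -0.8, -0.15, -0.5, 0.4, -0.3, -0.3)
  )
}

default_worktype_pool <- function() {
  tibble(
    work_type = c("waterway", "fishery", "agriculture", "transportation",
                  "forestry", "utility", "ocean", "development", "recreation",
                  "military"),
    weight = c(5, 1.5, 1, 1, 0.8, 0.7, 0.6, 0.6, 0.5, 0.3)
  )
}

default_region_pool <- function() {
  tibble(
    region = c("Northwest", "Southwest", "West Coast", "Northeast",
               "Southeast", "Alaska", "Pacific Island"),
    weight = c(2, 1.5, 1, 1, 1.5, 0.8, 0.7)
  )
}

default_enrichment <- function() {
  tibble(
    species = c("Chinook salmon", "Coho salmon", "Steelhead"),
    work_type = "agriculture",
    multiplier = 8
  )
}

#' Build a synthetic-data configuration
#'
#' Assembles and validates every generative parameter of the synthetic
#' consultation-record generator.  Defaults emulate the observed consultation
#' regime: ~19.9% of consultations formal, determination categories dominated
#' by NLAA, jeopardy findings on the order of 1.5% of formal consultations,
#' agency and work-type frequencies strongly skewed, salmonid species split
#' into multiple DPS/ESUs, agriculture-work enrichment of salmonid jeopardy,
#' and a shared jeopardy shock across Pacific salmonids.
#'
#' @param n_consultations Number of consultations to generate (>= 0).
#' @param year_range Inclusive integer pair of start years.
#' @param species_pool Tibble with columns `species` and `dps` (list column of
#'   DPS/ESU labels; empty vector = species listed as a whole).
#' @param agency_pool Tibble with columns `agency`, `weight` (>= 0) and
#'   `bias` in \[-1, 1\]: negative bias makes the agency's proposals tend to
#'   fall below the latent expert category (underestimation), positive above.
#' @param worktype_pool Tibble with columns `work_type`, `weight`.
#' @param region_pool Tibble with columns `region`, `weight`.
#' @param p_formal Probability a consultation is formal.
#' @param base_determination_probs Probability vector over the four expert
#'   categories (`no effect`, `NLAA`, `no jeopardy`, `jeopardy`), summing to 1.
#'   Informal consultations draw from the first two categories renormalised;
#'   formal consultations draw from all four.
#' @param noise Probability that an agency proposal deviates from the
#'   category agreeing with the latent expert category.
#' @param p_proposed_jeopardy Probability that an LAA-range proposal is
#'   emitted as a direct "proposed (no) jeopardy" category instead of LAA;
#'   these columns are very rare in practice.
#' @param species_mean,species_max Mean (truncated-geometric) and maximum of
#'   the species-per-consultation count.
#' @param p_extra_dps Per-additional-unit inclusion probability for species
#'   with multiple DPS/ESUs.
#' @param p_designated_ch Probability a species row has designated critical
#'   habitat at consultation time.
#' @param p_adverse_mod_given_jeopardy,p_adverse_mod_given_no_jeopardy
#'   Conditional probabilities of an adverse-modification habitat finding.
#' @param p_date_error Probability the recorded start/end dates are swapped
#'   (exercises the date-correction cleaning step).
#' @param jeopardy_enrichment Tibble with columns `species`, `work_type`,
#'   `multiplier` (>= 0): multiplies the conditional jeopardy probability for
#'   matching determinations before renormalisation.
#' @param cojeopardy_groups List of character vectors of species names; each
#'   group shares a per-consultation jeopardy shock.
#' @param cojeopardy_shock_prob Per-consultation probability the shock fires.
#' @param cojeopardy_multiplier Jeopardy multiplier applied to group members
#'   when the shock fires.
#' @param seed Integer seed; together with the record index it determines one
#'   RNG stream per consultation, so identical configurations yield
#'   byte-identical output regardless of generation order.
#' @return A validated `synthetic_config` object (a named list).
#' @seealso [generate_consultations()]
#' @export
synthetic_config <- function(n_consultations = 1000,
                             year_range = c(2000L, 2017L),
                             species_pool = default_species_pool(),
                             agency_pool = default_agency_pool(),
                             worktype_pool = default_worktype_pool(),
                             region_pool = default_region_pool(),
                             p_formal = 0.199,
                             base_determination_probs =
                               c("no effect" = 0.134, "NLAA" = 0.685,
                                 "no jeopardy" = 0.177, "jeopardy" = 0.004),
                             noise = 0.21,
                             p_proposed_jeopardy = 3e-4,
                             species_mean = 2,
                             species_max = 25,
                             p_extra_dps = 0.3,
                             p_designated_ch = 0.5,
                             p_adverse_mod_given_jeopardy = 0.6,
                             p_adverse_mod_given_no_jeopardy = 0.01,
                             p_date_error = 0.005,
                             jeopardy_enrichment = default_enrichment(),
                             cojeopardy_groups = list(c(
                               "Chinook salmon", "Steelhead", "Coho salmon",
                               "Sockeye salmon", "Chum salmon")),
                             cojeopardy_shock_prob = 0.01,
                             cojeopardy_multiplier = 40,
                             seed = 1L) {
  cfg <- list(
    n_consultations = n_consultations, year_range = year_range,
    species_pool = as_tibble(species_pool),
    agency_pool = as_tibble(agency_pool),
    worktype_pool = as_tibble(worktype_pool),
    region_pool = as_tibble(region_pool),
    p_formal = p_formal,
    base_determination_probs = base_determination_probs,
    noise = noise, p_proposed_jeopardy = p_proposed_jeopardy,
    species_mean = species_mean, species_max = species_max,
    p_extra_dps = p_extra_dps, p_designated_ch = p_designated_ch,
    p_adverse_mod_given_jeopardy = p_adverse_mod_given_jeopardy,
    p_adverse_mod_given_no_jeopardy = p_adverse_mod_given_no_jeopardy,
    p_date_error = p_date_error,
    jeopardy_enrichment = as_tibble(jeopardy_enrichment),
    cojeopardy_groups = cojeopardy_groups,
    cojeopardy_shock_prob = cojeopardy_shock_prob,
    cojeopardy_multiplier = cojeopardy_multiplier,
    seed = seed
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  n <- cfg$n_consultations
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    stop_config("n_consultations", "must be a single non-negative integer")
  }
  yr <- cfg$year_range
  if (!is.numeric(yr) || length(yr) != 2 || any(is.na(yr)) || yr[1] > yr[2]) {
    stop_config("year_range", "must be an inclusive integer pair (lo <= hi)")
  }
  if (nrow(cfg$species_pool) == 0) stop_config("species_pool", "must be non-empty")
  for (pool in c("agency_pool", "worktype_pool", "region_pool")) {
    p <- cfg[[pool]]
    if (nrow(p) == 0) stop_config(pool, "must be non-empty")
    if (any(p$weight < 0) || sum(p$weight) <= 0) {
      stop_config(pool, "weights must be non-negative with positive sum")
    }
  }
  if (any(abs(cfg$agency_pool$bias) > 1)) {
    stop_config("agency_pool", "bias must lie in [-1, 1]")
  }
  bp <- cfg$base_determination_probs
  if (length(bp) != 4 || any(bp < 0) || abs(sum(bp) - 1) > 1e-9) {
    stop_config("base_determination_probs",
                "must be 4 non-negative probabilities summing to 1")
  }
  for (f in c("p_formal", "noise", "p_proposed_jeopardy", "p_extra_dps",
              "p_designated_ch", "p_adverse_mod_given_jeopardy",
              "p_adverse_mod_given_no_jeopardy", "p_date_error",
              "cojeopardy_shock_prob")) {
    if (!is_prob(cfg[[f]])) stop_config(f, "must be a probability in [0, 1]")
  }
  if (nrow(cfg$jeopardy_enrichment) > 0 &&
      any(cfg$jeopardy_enrichment$multiplier < 0)) {
    stop_config("jeopardy_enrichment", "multipliers must be >= 0")
  }
  if (cfg$cojeopardy_multiplier < 0) {
    stop_config("cojeopardy_multiplier", "must be >= 0")
  }
  if (cfg$species_mean < 1) stop_config("species_mean", "must be >= 1")
  invisible(cfg)
}

#' Load a synthetic configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [synthetic_config()]; pools may be given as lists of records.
#'
#' @param path Path to a YAML file.
#' @return A `synthetic_config` object.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (pool in c("species_pool", "agency_pool", "worktype_pool",
                 "region_pool", "jeopardy_enrichment")) {
    if (!is.null(raw[[pool]]) && !is.data.frame(raw[[pool]])) {
      rows <- lapply(raw[[pool]], function(r) {
        if (!is.null(r$dps)) r$dps <- list(as.character(unlist(r$dps)))
        as_tibble(r)
      })
      raw[[pool]] <- bind_rows(rows)
    }
  }
  if (!is.null(raw$base_determination_probs)) {
    raw$base_determination_probs <-
      setNames(as.numeric(unlist(raw$base_determination_probs)),
               expert_categories())
  }
  if (!is.null(raw$cojeopardy_groups)) {
    raw$cojeopardy_groups <- lapply(raw$cojeopardy_groups, as.character)
  }
  do.call(synthetic_config, raw)
}

record_columns <- function() {
  c("consultation_id", "agency", "region", "work_type", "consultation_type",
    "type", "complexity", "start_date", "end_date", "species", "dps_esu",
    "agency_proposed", "expert_final", "critical_habitat")
}

empty_records <- function() {
  tibble(
    consultation_id = character(), agency = character(), region = character(),
    work_type = character(), consultation_type = character(),
    type = character(), complexity = character(),
    start_date = as.Date(character()), end_date = as.Date(character()),
    species = character(), dps_esu = character(),
    agency_proposed = character(), expert_final = character(),
    critical_habitat = character()
  )
}

#' Generate synthetic consultation records
#'
#' Draws `n_consultations` consultation records from the generative model in
#' `config`.  The latent expert category of each determination is generated
#' first; the agency proposal is then generated conditionally through an
#' ordinal shift kernel: with probability `noise` the proposal moves one step
#' up (probability `(1+bias)/2`) or down (`(1-bias)/2`) the agency severity
#' order from the category that agrees with the expert category; a step off
#' the end of the scale leaves the proposal in agreement.  With `noise = 0`
#' and all biases 0 every determination pair therefore has discrepancy score
#' 0.  Enrichment multipliers and co-jeopardy shocks scale the conditional
#' jeopardy probability before renormalisation.
#'
#' @param config A [synthetic_config()] object.
#' @return A tibble with one row per (consultation, species, DPS/ESU)
#'   determination; columns per `record_columns()`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_consultations = 5, seed = 42)
#' generate_consultations(cfg)
generate_consultations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  n <- config$n_consultations
  if (n == 0) return(empty_records())

  sp_names <- config$species_pool$species
  sp_dps <- config$species_pool$dps
  n_sp_pool <- length(sp_names)
  ag <- config$agency_pool
  wt <- config$worktype_pool
  rg <- config$region_pool
  ag_w <- ag$weight / sum(ag$weight)
  wt_w <- wt$weight / sum(wt$weight)
  rg_w <- rg$weight / sum(rg$weight)
  bp <- unname(config$base_determination_probs)
  bp_informal <- bp[1:2] / sum(bp[1:2])
  complexities <- consultation_complexities()
  cx_w <- c(0.90, 0.06, 0.03, 0.01)

  # enrichment lookup keyed on "species\rwork_type"
  enr <- config$jeopardy_enrichment
  enr_key <- if (nrow(enr) > 0) {
    setNames(enr$multiplier, paste(enr$species, enr$work_type, sep = "\r"))
  } else {
    numeric(0)
  }
  groups <- config$cojeopardy_groups
  n_groups <- length(groups)
  # species index -> group id (first matching group), 0 = none
  sp_group <- integer(n_sp_pool)
  if (n_groups > 0) {
    for (g in seq_len(n_groups)) {
      sp_group[sp_names %in% groups[[g]] & sp_group == 0L] <- g
    }
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(record_seed(config$seed, i))
    yr <- if (config$year_range[1] == config$year_range[2]) {
      config$year_range[1]
    } else {
      sample(seq(config$year_range[1], config$year_range[2]), 1L)
    }
    start <- as.Date(sprintf("%d-01-01", yr)) + (sample.int(365L, 1L) - 1L)
    end <- start + rpois(1L, 90)
    if (runif(1) < config$p_date_error) {
      tmp <- start; start <- end; end <- tmp
    }
    agency_i <- sample.int(nrow(ag), 1L, prob = ag_w)
    work <- wt$work_type[sample.int(nrow(wt), 1L, prob = wt_w)]
    region <- rg$region[sample.int(nrow(rg), 1L, prob = rg_w)]
    formal <- runif(1) < config$p_formal
    complexity <- complexities[sample.int(4L, 1L, prob = cx_w)]

    n_species <- min(1L + rgeom(1L, 1 / config$species_mean),
                     config$species_max, n_sp_pool)
    sp_idx <- sample.int(n_sp_pool, n_species)
    # a co-jeopardy shock is a joint exposure: it fires per consultation and
    # applies only when the consultation involves >= 2 members of the group
    # (otherwise it would merely inflate single-species margins, which the
    # fixed-margin null absorbs)
    shocked <- if (n_groups > 0) {
      grp_present <- tabulate(sp_group[sp_idx], nbins = n_groups)
      runif(n_groups) < config$cojeopardy_shock_prob & grp_present >= 2L
    } else {
      logical(0)
    }

    species_v <- character(0); dps_v <- character(0)
    expert_v <- character(0); prop_v <- character(0); ch_v <- character(0)
    for (s in sp_idx) {
      dps <- sp_dps[[s]]
      k <- length(dps)
      nd <- if (k <= 1) 1L else 1L + rbinom(1L, k - 1L, config$p_extra_dps)
      labels <- if (k == 0) NA_character_ else dps[sample.int(k, nd)]

      if (formal) {
        pj <- bp[4]
        mult <- enr_key[paste(sp_names[s], work, sep = "\r")]
        if (!is.na(mult)) pj <- pj * unname(mult)
        if (sp_group[s] > 0 && shocked[sp_group[s]]) {
          pj <- pj * config$cojeopardy_multiplier
        }
        probs <- c(bp[1:3], pj)
        expert_idx <- sample.int(4L, nd, replace = TRUE, prob = probs)
      } else {
        expert_idx <- sample.int(2L, nd, replace = TRUE, prob = bp_informal)
      }
      expert <- expert_categories()[expert_idx]

      agree <- c(1L, 2L, 3L, 3L)[expert_idx]
      dev <- runif(nd) < config$noise
      dir <- ifelse(runif(nd) < (1 + ag$bias[agency_i]) / 2, 1L, -1L)
      pos <- agree + ifelse(dev, dir, 0L)
      off <- pos < 1L | pos > 3L
      pos[off] <- agree[off]
      proposal <- c("no effect", "NLAA", "LAA")[pos]
      rare <- proposal == "LAA" & runif(nd) < config$p_proposed_jeopardy
      proposal[rare & expert == "jeopardy"] <- "proposed jeopardy"
      proposal[rare & expert != "jeopardy"] <- "proposed no jeopardy"

      designated <- runif(nd) < config$p_designated_ch
      am_draw <- runif(nd)
      ch <- ifelse(!designated, "no critical habitat",
             ifelse(expert == "jeopardy",
                    ifelse(am_draw < config$p_adverse_mod_given_jeopardy,
                           "adverse modification", "no adverse modification"),
             ifelse(expert == "no jeopardy",
                    ifelse(am_draw < config$p_adverse_mod_given_no_jeopardy,
                           "adverse modification", "no adverse modification"),
                    expert)))

      species_v <- c(species_v, rep(sp_names[s], nd))
      dps_v <- c(dps_v, labels)
      expert_v <- c(expert_v, expert)
      prop_v <- c(prop_v, proposal)
      ch_v <- c(ch_v, ch)
    }

    nr <- length(species_v)
    type <- if (formal) "formal" else "informal"
    ctype <- paste0(toupper(substring(type, 1, 1)), substring(type, 2))
    if (complexity != "standard") {
      ctype <- paste(ctype, paste0(toupper(substring(complexity, 1, 1)),
                                   substring(complexity, 2)))
    }
    out[[i]] <- list(
      consultation_id = rep(sprintf("C%06d", i), nr),
      agency = rep(ag$agency[agency_i], nr),
      region = rep(region, nr),
      work_type = rep(work, nr),
      consultation_type = rep(ctype, nr),
      type = rep(type, nr),
      complexity = rep(complexity, nr),
      start_date = rep(start, nr),
      end_date = rep(end, nr),
      species = species_v,
      dps_esu = dps_v,
      agency_proposed = prop_v,
      expert_final = expert_v,
      critical_habitat = ch_v
    )
  }

  tibble(
    consultation_id = unlist(lapply(out, `[[`, "consultation_id")),
    agency = unlist(lapply(out, `[[`, "agency")),
    region = unlist(lapply(out, `[[`, "region")),
    work_type = unlist(lapply(out, `[[`, "work_type")),
    consultation_type = unlist(lapply(out, `[[`, "consultation_type")),
    type = unlist(lapply(out, `[[`, "type")),
    complexity = unlist(lapply(out, `[[`, "complexity")),
    start_date = as.Date(unlist(lapply(out, function(x) as.character(x$start_date)))),
    end_date = as.Date(unlist(lapply(out, function(x) as.character(x$end_date)))),
    species = unlist(lapply(out, `[[`, "species")),
    dps_esu = unlist(lapply(out, `[[`, "dps_esu")),
    agency_proposed = unlist(lapply(out, `[[`, "agency_proposed")),
    expert_final = unlist(lapply(out, `[[`, "expert_final")),
    critical_habitat = unlist(lapply(out, `[[`, "critical_habitat"))
  )
}

#' Write consultation records to a CSV fixture
#'
#' Writes the one-row-per-determination CSV dialect (UTF-8, header row,
#' ISO-8601 dates) that [parse_records()] reads back losslessly.
#'
#' @param records Record tibble from [generate_consultations()] or
#'   [parse_records()].
#' @param path Destination file path.
#' @param allow_empty Permit writing a header-only file for empty input.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(records, path, allow_empty = FALSE) {
  if (nrow(records) == 0 && !allow_empty) {
    abort("refusing to write an empty fixture; set `allow_empty = TRUE`")
  }
  cols <- setdiff(record_columns(), c("type", "complexity"))
  readr::write_csv(records[, cols], path, na = "")
  invisible(path)
}
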