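# Parsing, cleaning and recoding of consultation-record exports.
#
# All operations are pure (inputs are never mutated) and idempotent, and
# every input row is either attached to the output or reported in a rejects
# log carried as an attribute — there are no silent drops.

extdata <- function(file) {
  system.file("extdata", file, package = "concord7", mustWork = TRUE)
}

#' Shipped lookup tables
#'
#' `default_alias_map()` returns the shipped raw-to-canonical name map for
#' species, agencies and work types; `default_determination_synonyms()` and
#' `default_critical_habitat_synonyms()` the determination-vocabulary maps.
#' All are two-column tibbles (`raw`, `canonical`) so site-specific
#' vocabularies can be supplied as plain CSVs without code changes.
#'
#' @return A tibble with columns `raw` and `canonical`.
#' @export
default_alias_map <- function() {
  readr::read_csv(extdata("alias_map.csv"), col_types = "cc", progress = FALSE)
}

#' @rdname default_alias_map
#' @export
default_determination_synonyms <- function() {
  readr::read_csv(extdata("determination_synonyms.csv"), col_types = "cc",
                  progress = FALSE)
}

#' @rdname default_alias_map
#' @export
default_critical_habitat_synonyms <- function() {
  readr::read_csv(extdata("critical_habitat_synonyms.csv"), col_types = "cc",
                  progress = FALSE)
}

rejects_log <- function(row = integer(), reason = character()) {
  tibble(row = as.integer(row), reason = as.character(reason))
}

#' Retrieve the rejects log of a parsed record set
#'
#' @param records A record tibble produced by [parse_records()].
#' @return Tibble with columns `row` and `reason` (empty when clean).
#' @export
rejects <- function(records) {
  attr(records, "rejects") %||% rejects_log()
}

#' Parse a consultation-record CSV
#'
#' Reads the one-row-per-determination CSV dialect written by
#' [write_fixture()] (or a raw export mapped onto the same columns), splits
#' the free-text consultation-type string into `type` and `complexity`, and
#' recodes determination vocabulary into the canonical categories.  Rows
#' with unrecognised determination strings are kept, their category set to
#' `"missing"`, and reported in the rejects log (`rejects(x)`).
#'
#' @param source Path to a CSV file.
#' @param determination_synonyms,critical_habitat_synonyms Two-column
#'   synonym tibbles (`raw`, `canonical`).
#' @return Record tibble (see `record_columns()`) with a `rejects` attribute.
#' @export
parse_records <- function(source,
                          determination_synonyms = default_determination_synonyms(),
                          critical_habitat_synonyms = default_critical_habitat_synonyms()) {
  required <- setdiff(record_columns(), c("type", "complexity"))
  raw <- suppressWarnings(readr::read_csv(
    source,
    col_types = readr::cols(
      .default = readr::col_character(),
      start_date = readr::col_date(format = "%Y-%m-%d"),
      end_date = readr::col_date(format = "%Y-%m-%d")
    ),
    progress = FALSE
  ))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("input is missing mandatory columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "concord7_schema_error")
  }

  log <- rejects_log()
  # malformed fields caught by the reader (e.g. unparseable dates) go into
  # the rejects log instead of surfacing as reader warnings
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    log <- bind_rows(log, rejects_log(
      probs$row - 1L,  # reader rows include the header
      sprintf("malformed field (expected %s)", probs$expected)))
  }
  split <- split_consultation_type(raw$consultation_type)
  raw$type <- split$type
  raw$complexity <- split$complexity
  bad_type <- which(split$type == "missing")
  if (length(bad_type) > 0) {
    log <- bind_rows(log, rejects_log(bad_type, "unrecognised consultation type"))
  }

  ap <- recode_species_determination(raw$agency_proposed, role = "agency",
                                     synonyms = determination_synonyms)
  bad_ap <- which(ap == "missing" & !is.na(raw$agency_proposed))
  if (length(bad_ap) > 0) {
    log <- bind_rows(log, rejects_log(bad_ap, "unmapped agency determination"))
  }
  ef <- recode_species_determination(raw$expert_final, role = "expert",
                                     synonyms = determination_synonyms)
  bad_ef <- which(ef == "missing" & !is.na(raw$expert_final))
  if (length(bad_ef) > 0) {
    log <- bind_rows(log, rejects_log(bad_ef, "unmapped or non-final expert determination"))
  }
  ch <- recode_critical_habitat(raw$critical_habitat,
                                had_designated_ch = TRUE,
                                synonyms = critical_habitat_synonyms)
  # the shipped dialect already carries the "no critical habitat" code
  bad_ch <- which(ch == "missing" & !is.na(raw$critical_habitat))
  if (length(bad_ch) > 0) {
    log <- bind_rows(log, rejects_log(bad_ch, "unmapped critical-habitat determination"))
  }

  out <- raw
  out$agency_proposed <- ap
  out$expert_final <- ef
  out$critical_habitat <- ch
  out <- out[, record_columns()]
  attr(out, "rejects") <- log
  out
}

#' Correct reversed consultation dates
#'
#' Records whose end date precedes the start date have the two dates swapped
#' and are flagged in a logical `date_corrected` column; records with an
#' unparseable/missing date keep `NA` and are excluded later by the
#' window-filter step, never dropped here.
#'
#' @param records Record tibble.
#' @return Record tibble with a `date_corrected` column.
#' @export
clean_dates <- function(records) {
  swap <- !is.na(records$start_date) & !is.na(records$end_date) &
    records$end_date < records$start_date
  out <- records
  s <- out$start_date[swap]
  out$start_date[swap] <- out$end_date[swap]
  out$end_date[swap] <- s
  out$date_corrected <- if ("date_corrected" %in% names(records)) {
    records$date_corrected | swap
  } else {
    swap
  }
  out
}

#' Homogenise species, agency and work-type names
#'
#' Applies a raw-to-canonical alias map to the `species`, `agency` and
#' `work_type` columns.  Strings absent from the map pass through unchanged
#' and are listed in the `unmapped` attribute; the operation is idempotent.
#'
#' @param records Record tibble.
#' @param alias_map Two-column tibble (`raw`, `canonical`).
#' @return Record tibble with canonical names.
#' @export
harmonize_names <- function(records, alias_map = default_alias_map()) {
  out <- records
  unmapped <- character(0)
  for (col in c("species", "agency", "work_type")) {
    x <- out[[col]]
    hit <- match(x, alias_map$raw)
    out[[col]] <- ifelse(is.na(hit), x, alias_map$canonical[hit])
    unmapped <- c(unmapped,
                  unique(x[is.na(hit) & !is.na(x) &
                             !(x %in% alias_map$canonical)]))
  }
  attr(out, "unmapped") <- unique(unmapped)
  out
}

#' Split the raw consultation-type string
#'
#' The tracking database records the nature of a consultation in a single
#' free-text field; this splits it into a `type` (formal / informal /
#' combined) and a `complexity` (standard / programmatic / conference /
#' early).  A type string with no complexity qualifier maps to `standard`;
#' an unrecognised string maps to `("missing", "missing")`.
#'
#' @param raw Character vector of consultation-type strings.
#' @return Tibble with columns `type` and `complexity`.
#' @export
#' @examples
#' split_consultation_type(c("Formal Programmatic", "Informal", ""))
split_consultation_type <- function(raw) {
  low <- tolower(trimws(ifelse(is.na(raw), "", raw)))
  type <- case_when(
    grepl("informal", low) ~ "informal",
    grepl("combined", low) ~ "combined",
    grepl("formal", low) ~ "formal",
    TRUE ~ "missing"
  )
  complexity <- case_when(
    type == "missing" ~ "missing",
    grepl("programmatic", low) ~ "programmatic",
    grepl("conference", low) ~ "conference",
    grepl("early", low) ~ "early",
    TRUE ~ "standard"
  )
  tibble(type = type, complexity = complexity)
}

#' Recode raw species-determination strings
#'
#' Maps raw determination vocabulary into the canonical categories through a
#' configurable synonym table.  Expert final determinations admit only the
#' four final categories: an "LAA" string in the expert column is non-final
#' (the expert agency must resolve LAA into jeopardy / no jeopardy) and maps
#' to `"missing"`.
#'
#' @param raw Character vector of raw determination strings.
#' @param role `"agency"` (five proposal categories) or `"expert"` (four
#'   final categories).
#' @param synonyms Two-column synonym tibble (`raw`, `canonical`).
#' @return Character vector of canonical categories, `"missing"` when
#'   unmapped or disallowed for the role.
#' @export
recode_species_determination <- function(raw, role = c("agency", "expert"),
                                         synonyms = default_determination_synonyms()) {
  role <- match.arg(role)
  allowed <- if (role == "agency") agency_categories() else expert_categories()
  key <- tolower(trimws(ifelse(is.na(raw), "", raw)))
  hit <- synonyms$canonical[match(key, tolower(synonyms$raw))]
  ifelse(is.na(hit) | !(hit %in% allowed), "missing", hit)
}

#' Recode raw critical-habitat determination strings
#'
#' Species without designated critical habitat at consultation time are
#' coded `"no critical habitat"` regardless of the raw string; otherwise the
#' raw string maps through the synonym table into the four habitat
#' categories.
#'
#' @param raw Character vector of raw habitat-determination strings.
#' @param had_designated_ch Logical (recycled): did the species have
#'   designated critical habitat at consultation time?
#' @param synonyms Two-column synonym tibble (`raw`, `canonical`).
#' @return Character vector of canonical habitat categories.
#' @export
recode_critical_habitat <- function(raw, had_designated_ch,
                                    synonyms = default_critical_habitat_synonyms()) {
  key <- tolower(trimws(ifelse(is.na(raw), "", raw)))
  hit <- synonyms$canonical[match(key, tolower(synonyms$raw))]
  mapped <- ifelse(is.na(hit), "missing", hit)
  ifelse(rep_len(!had_designated_ch, length(mapped)),
         "no critical habitat", mapped)
}

#' Collapse DPS/ESU rows to species level
#'
#' For frequency analyses all DPS/ESUs of a species are considered together:
#' a consultation involving several population units of one species counts
#' as a single consultation for that species.  Determination-level analyses
#' keep the original rows; this helper returns the collapsed
#' consultation-by-species view.
#'
#' @param records Record tibble.
#' @return Tibble with one row per (consultation, species): consultation
#'   fields, `n_determinations`, and `any_jeopardy` / `any_adverse_mod`
#'   indicator columns.
#' @export
aggregate_dps <- function(records) {
  records |>
    group_by(.data$consultation_id, .data$species) |>
    summarise(
      agency = .data$agency[1], region = .data$region[1],
      work_type = .data$work_type[1], type = .data$type[1],
      start_date = .data$start_date[1],
      n_determinations = n(),
      any_jeopardy = any(.data$expert_final == "jeopardy"),
      any_adverse_mod = any(.data$critical_habitat == "adverse modification"),
      .groups = "drop"
    )
}

#' Aggregate legacy regions into West Coast
#'
#' The Southwest and Northwest administrative regions were merged into a
#' single West Coast region in 2013; for consistency across years all
#' records from those regions are relabelled `"West Coast"`.  Idempotent.
#'
#' @param records Record tibble.
#' @return Record tibble with harmonised regions.
#' @export
aggregate_regions <- function(records) {
  out <- records
  out$region <- ifelse(out$region %in% c("Southwest", "Northwest"),
                       "West Coast", out$region)
  out
}

#' Restrict records to the analysis window
#'
#' Keeps records whose consultation start date falls inside the closed
#' window.  Records with a missing start date cannot be windowed and are
#' excluded, with the count recorded in the `n_excluded_missing_date`
#' attribute.
#'
#' @param records Record tibble.
#' @param start,end Window bounds (coerced with [as.Date()]).
#' @return Filtered record tibble.
#' @export
filter_period <- function(records, start = "2000-01-01", end = "2017-06-30") {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) abort("window start must not exceed window end")
  keep <- !is.na(records$start_date) &
    records$start_date >= start & records$start_date <= end
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded_missing_date") <- sum(is.na(records$start_date))
  out
}
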