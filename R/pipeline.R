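# End-to-end pipeline: synthetic generation (or CSV input) -> cleaning ->
# concordance -> outcomes -> enrichment -> co-occurrence, with a JSON
# manifest recording provenance for every run.

#' Build a pipeline run configuration
#'
#' @param synthetic A [synthetic_config()] used to generate input records,
#'   or `NULL` when `input` is given.
#' @param input Path to a record CSV (alternative to `synthetic`).
#' @param out_dir Output directory (created if absent); every output file is
#'   written inside it.
#' @param window Analysis window, length-2 character/Date vector.
#' @param min_n_ks Minimum per-agency determinations for the KS stage.
#' @param n_perm Number of fixed-margin permutations for enrichment.
#' @param seed Seed for the enrichment permutations.
#' @param p_convention Enrichment p-value convention (see
#'   [permutation_enrichment()]).
#' @param cooccur_universe Column universe for the co-occurrence stage.
#' @param stages Named logical toggles: `concordance`, `outcomes`,
#'   `enrichment`, `cooccurrence`.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = synthetic_config(),
                       input = NULL,
                       out_dir = tempfile("concord7-run-"),
                       window = c("2000-01-01", "2017-06-30"),
                       min_n_ks = 20,
                       n_perm = 1000,
                       seed = 1L,
                       p_convention = "greater",
                       cooccur_universe = "jeopardy",
                       stages = c(concordance = TRUE, outcomes = TRUE,
                                  enrichment = TRUE, cooccurrence = TRUE)) {
  if (is.null(synthetic) && is.null(input)) {
    abort("one of `synthetic` or `input` is required")
  }
  if (!is.null(input) && !file.exists(input)) {
    abort(sprintf("input file does not exist: %s", input))
  }
  structure(list(synthetic = synthetic, input = input, out_dir = out_dir,
                 window = window, min_n_ks = min_n_ks, n_perm = n_perm,
                 seed = seed, p_convention = p_convention,
                 cooccur_universe = cooccur_universe, stages = stages),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; a `synthetic` block is
#' passed through [read_synthetic_config()] semantics.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic)) {
    tmp <- tempfile(fileext = ".yml")
    on.exit(unlink(tmp))
    yaml::write_yaml(raw$synthetic, tmp)
    raw$synthetic <- read_synthetic_config(tmp)
  }
  if (!is.null(raw$stages)) raw$stages <- unlist(raw$stages)
  do.call(run_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes data preparation, concordance, outcome, enrichment and
#' co-occurrence stages in order, writing one CSV/JSON per output table
#' plus a `manifest.json` recording the package version, seeds, per-stage
#' status and row counts, and every emitted file.  Outputs are
#' deterministic given the configuration and seeds.  A stage failure aborts
#' the run with the stage name; the manifest written so far marks the run
#' incomplete.
#'
#' @param config A [run_config()].
#' @return The output directory path, invisibly; the manifest (as a list)
#'   is attached as the `manifest` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- new.env(parent = emptyenv())
  st$manifest <- list(
    package = "concord7",
    version = as.character(utils::packageVersion("concord7")),
    seed = config$seed,
    n_perm = config$n_perm,
    window = as.character(config$window),
    complete = FALSE,
    stages = list(),
    files = character(0),
    rows = list()
  )
  finish <- function() {
    jsonlite::write_json(st$manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e) {
      st$manifest$stages[[name]] <- list(status = "error",
                                       message = conditionMessage(e))
      finish()
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "concord7_stage_error")
    })
    st$manifest$stages[[name]] <- list(status = "ok")
    res
  }

  records <- stage("prepare", {
    rec <- if (!is.null(config$input)) {
      parse_records(config$input)
    } else {
      generate_consultations(config$synthetic)
    }
    st$manifest$rows$input <- nrow(rec)
    rej <- rejects(rec)
    readr::write_csv(rej, file.path(config$out_dir, "rejects.csv"))
    st$manifest$files <- c(st$manifest$files, "rejects.csv")
    rec <- rec |> clean_dates() |> harmonize_names() |> aggregate_regions()
    rec <- filter_period(rec, config$window[1], config$window[2])
    st$manifest$rows$analyzed <- nrow(rec)
    st$manifest$rows$rejected <- nrow(rej)
    readr::write_csv(rec, file.path(config$out_dir, "records_clean.csv"))
    st$manifest$files <- c(st$manifest$files, "records_clean.csv")
    rec
  })

  if (isTRUE(config$stages[["concordance"]])) {
    stage("concordance", {
      pairs <- determination_pairs(records)
      tab <- build_concordance_table(pairs)
      write_concordance_table(tab, file.path(config$out_dir,
                                             "concordance_table.csv"))
      kap <- weighted_kappa(tab)
      readr::write_csv(
        tibble(kappa = kap$kappa, observed = kap$observed,
               expected = kap$expected, N = kap$N),
        file.path(config$out_dir, "kappa.csv"))
      readr::write_csv(score_distribution(pairs),
                       file.path(config$out_dir, "score_distribution.csv"))
      readr::write_csv(ks_by_agency(pairs, min_n = config$min_n_ks),
                       file.path(config$out_dir, "ks_by_agency.csv"))
      st$manifest$files <- c(st$manifest$files, "concordance_table.csv",
                           "kappa.csv", "score_distribution.csv",
                           "ks_by_agency.csv")
    })
  } else {
    st$manifest$stages$concordance <- list(status = "skipped")
  }

  if (isTRUE(config$stages[["outcomes"]])) {
    stage("outcomes", {
      for (key in c("species", "agency", "work_type")) {
        readr::write_csv(frequency_table(records, key),
                         file.path(config$out_dir,
                                   sprintf("frequency_%s.csv", key)))
        st$manifest$files <- c(st$manifest$files, sprintf("frequency_%s.csv", key))
      }
      summ <- consultation_outcome_summary(records)
      jsonlite::write_json(summ, file.path(config$out_dir,
                                           "outcome_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      st$manifest$files <- c(st$manifest$files, "outcome_summary.json")
      yearly <- records |>
        distinct(.data$consultation_id, .keep_all = TRUE) |>
        filter(!is.na(.data$start_date)) |>
        mutate(year = as.integer(format(.data$start_date, "%Y"))) |>
        count(.data$year, .data$type)
      trends <- list()
      for (tp in c("informal", "formal")) {
        series <- yearly |> filter(.data$type == tp) |>
          rename(count = "n") |> select("year", "count")
        if (length(unique(series$year)) >= 3) {
          tr <- fit_yearly_counts(series, "poisson-log")
          tr$series <- tp
          trends[[tp]] <- tr
        }
      }
      if (length(trends) > 0) {
        readr::write_csv(bind_rows(trends),
                         file.path(config$out_dir, "trend_fits.csv"))
        st$manifest$files <- c(st$manifest$files, "trend_fits.csv")
      }
    })
  } else {
    st$manifest$stages$outcomes <- list(status = "skipped")
  }

  if (isTRUE(config$stages[["enrichment"]])) {
    stage("enrichment", {
      jm <- build_jeopardy_matrix(records)
      if (sum(jm) > 0) {
        enr <- permutation_enrichment(jm, n_perm = config$n_perm,
                                      seed = config$seed,
                                      convention = config$p_convention)
        readr::write_csv(enr, file.path(config$out_dir, "enrichment.csv"))
        st$manifest$files <- c(st$manifest$files, "enrichment.csv")
      } else {
        st$manifest$stages$enrichment <- list(status = "empty")
      }
    })
  } else {
    st$manifest$stages$enrichment <- list(status = "skipped")
  }

  if (isTRUE(config$stages[["cooccurrence"]])) {
    stage("cooccurrence", {
      bm <- build_binary_matrix(records, universe = config$cooccur_universe)
      if (nrow(bm) >= 2) {
        pairs <- all_pairs(bm)
        readr::write_csv(pairs, file.path(config$out_dir, "cooccurrence.csv"))
        st$manifest$files <- c(st$manifest$files, "cooccurrence.csv")
      } else {
        st$manifest$stages$cooccurrence <- list(status = "empty")
      }
    })
  } else {
    st$manifest$stages$cooccurrence <- list(status = "skipped")
  }

  st$manifest$complete <- TRUE
  finish()
  out <- config$out_dir
  attr(out, "manifest") <- st$manifest
  invisible(out)
}
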