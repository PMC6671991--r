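test_that("generator handles the empty and degenerate cases", {
  cfg <- synthetic_config(n_consultations = 0)
  rec <- generate_consultations(cfg)
  expect_equal(nrow(rec), 0)
  expect_named(rec, c("consultation_id", "agency", "region", "work_type",
                      "consultation_type", "type", "complexity", "start_date",
                      "end_date", "species", "dps_esu", "agency_proposed",
                      "expert_final", "critical_habitat"))
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synthetic_config(n_consultations = -1), "n_consultations")
  expect_error(synthetic_config(p_formal = 1.3), "p_formal")
  expect_error(
    synthetic_config(base_determination_probs = c(0.5, 0.5, 0.2, 0)),
    "base_determination_probs")
  expect_error(
    synthetic_config(agency_pool = tibble::tibble(
      agency = "A", weight = -1, bias = 0)),
    "agency_pool")
  expect_error(
    synthetic_config(species_pool = tibble::tibble(
      species = character(), dps = list())),
    "species_pool")
  expect_error(
    synthetic_config(agency_pool = tibble::tibble(
      agency = "A", weight = 1, bias = 2)),
    "bias")
})

test_that("identical configurations generate byte-identical records", {
  cfg <- synthetic_config(n_consultations = 200, seed = 11)
  a <- generate_consultations(cfg)
  b <- generate_consultations(cfg)
  expect_identical(a, b)
  # a different seed changes the draw
  c2 <- generate_consultations(synthetic_config(n_consultations = 200,
                                                seed = 12))
  expect_false(identical(a, c2))
})

test_that("zero noise and zero bias give perfect agreement everywhere", {
  rec <- generate_consultations(perfect_agreement_config(1, n = 500))
  pairs <- determination_pairs(rec)
  expect_gt(nrow(pairs), 0)
  expect_true(all(pairs$score == 0))
  tab <- build_concordance_table(pairs)
  expect_equal(weighted_kappa(tab)$kappa, 1)
})

test_that("every record respects the category enumerations and structure", {
  cfg <- synthetic_config(n_consultations = 300, seed = 5)
  rec <- generate_consultations(cfg)
  expect_equal(length(unique(rec$consultation_id)), 300)
  expect_true(all(rec$agency_proposed %in% agency_categories()))
  expect_true(all(rec$expert_final %in% expert_categories()))
  expect_true(all(rec$critical_habitat %in% critical_habitat_categories()))
  expect_true(all(rec$type %in% c("formal", "informal")))
  # jeopardy-range expert findings only arise in formal consultations
  expect_true(all(rec$type[rec$expert_final %in%
                             c("no jeopardy", "jeopardy")] == "formal"))
})

test_that("agency and work-type frequencies converge to configured weights", {
  cfg <- synthetic_config(n_consultations = 10000, seed = 3,
                          p_date_error = 0)
  rec <- generate_consultations(cfg)
  cons <- dplyr::distinct(rec, consultation_id, agency, work_type)
  for (col in c("agency", "work_type")) {
    pool <- if (col == "agency") cfg$agency_pool else cfg$worktype_pool
    obs <- table(factor(cons[[col]], levels = pool[[col]]))
    gof <- chisq_gof(as.integer(obs), expected = pool$weight)
    expect_gt(gof$p, 0.001)
  }
})

test_that("fixtures round-trip losslessly through the parser", {
  cfg <- synthetic_config(n_consultations = 40, seed = 9)
  rec <- generate_consultations(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture(rec, path)
  back <- parse_records(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(nrow(rejects(back)), 0)
  for (col in names(rec)) {
    expect_equal(back[[col]], rec[[col]], label = col)
  }
  # empty fixture requires the explicit flag, then writes a header-only file
  empty <- generate_consultations(synthetic_config(n_consultations = 0))
  expect_error(write_fixture(empty, path))
  write_fixture(empty, path, allow_empty = TRUE)
  expect_equal(nrow(parse_records(path)), 0)
})

test_that("negative agency bias produces majority-negative disagreements", {
  shares <- vapply(1:5, function(s) {
    rec <- generate_consultations(
      focused_config(s, n = 2000, bias = -0.6, noise = 0.3))
    underestimation_share(determination_pairs(rec)$score)
  }, 0)
  expect_true(all(shares > 0.5))
  # and symmetric positive bias flips the direction
  rec <- generate_consultations(
    focused_config(1, n = 2000, bias = 0.6, noise = 0.3))
  expect_lt(underestimation_share(determination_pairs(rec)$score), 0.5)
})

test_that("YAML synthetic configurations load to the same generator draw", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "n_consultations: 25",
    "seed: 4",
    "p_formal: 0.4",
    "noise: 0.1",
    "species_pool:",
    "  - species: Chinook salmon",
    "    dps: [Puget Sound ESU, Snake River fall-run ESU]",
    "  - species: Eulachon",
    "    dps: []",
    "agency_pool:",
    "  - {agency: Army Corps of Engineers, weight: 2, bias: 0.2}",
    "  - {agency: NMFS, weight: 1, bias: -0.2}",
    "worktype_pool:",
    "  - {work_type: waterway, weight: 1}",
    "region_pool:",
    "  - {region: Alaska, weight: 1}"
  ), path)
  cfg <- read_synthetic_config(path)
  expect_s3_class(cfg, "synthetic_config")
  rec <- generate_consultations(cfg)
  expect_equal(length(unique(rec$consultation_id)), 25)
  expect_true(all(rec$region == "Alaska"))
  expect_true(all(rec$species %in% c("Chinook salmon", "Eulachon")))
})
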