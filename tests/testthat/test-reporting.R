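test_that("a single consumed food carries the whole contribution share", {
  rec <- tibble::tibble(individual_id = "A", day_index = 1L,
                        food = "Grains>Pasta",
                        amount_cooked = 100, amount_raw = 100)
  s <- new_survey(tiny_individuals(), rec, n_days = 1)
  ctr <- contributors(s, tiny_index(), "cadmium")
  expect_equal(nrow(ctr), 1L)
  expect_equal(ctr$share, 1)
  expect_equal(ctr$rank, 1L)
})

test_that("contribution shares sum to one across foods", {
  s <- simulate_survey(population_spec(n_individuals = 200, seed = 14))
  idx <- build_index(normalize_concentrations(synthetic_study_concentrations()))
  for (substance in c("iodine", "t_arsenic", "mercury")) {
    ctr <- contributors(s, idx, substance)
    expect_equal(sum(ctr$share), 1, tolerance = 1e-9)
    expect_equal(ctr$rank, seq_len(nrow(ctr)))
    expect_true(all(diff(ctr$mean_contribution) <= 1e-12))
  }
})

test_that("seaweed foods dominate total-arsenic exposure after substitution", {
  idx <- build_index(normalize_concentrations(synthetic_study_concentrations()))
  # constructed fixture: pasta mass large enough that 10% of it, at the
  # seaweed concentration, outweighs every other source
  rec <- tibble::tibble(individual_id = c("A", "A", "B"),
                        day_index = c(1L, 1L, 1L),
                        food = c("Grains>Pasta", "Fish>Sea fish",
                                 "Grains>Pasta"),
                        amount_cooked = c(200, 10, 150),
                        amount_raw = c(100, 10, 75))
  s <- new_survey(tiny_individuals(), rec, n_days = 1)
  alt <- apply_scenario(s, seaweed_scenario())
  ctr <- contributors(alt, idx, "t_arsenic")
  expect_equal(ctr$food[1], "Algae>Seaweed pasta")

  # on the default synthetic population, fish and the two main seaweed
  # analogues are the leading sources under the alternative scenario
  s2 <- simulate_survey(population_spec(n_individuals = 400, seed = 15))
  top3 <- contributors(apply_scenario(s2, seaweed_scenario()), idx,
                       "t_arsenic", top_k = 3)$food
  expect_setequal(top3, c("Fish>Sea fish", "Algae>Seaweed pasta",
                          "Algae>Seaweed bacon"))
})

test_that("pipeline is invariant when the replacement matches the target", {
  s <- simulate_survey(population_spec(n_individuals = 150, seed = 16))
  conc <- synthetic_study_concentrations()
  # make seaweed pasta chemically identical to pasta (wet basis)
  pasta <- conc$food == "Grains>Pasta"
  swp <- conc$food == "Algae>Seaweed pasta"
  conc$value[swp] <- conc$value[pasta][match(conc$substance[swp],
                                             conc$substance[pasta])]
  conc$basis[swp] <- "wet"
  conc$censoring[swp] <- "measured"
  conc$censor_limit[swp] <- NA
  idx <- build_index(normalize_concentrations(conc))
  only_pasta <- scenario("swap", substitution_rule(
    "Grains>Pasta", "Algae>Seaweed pasta", 0.10))
  ref <- estimate_usual_intake(s, idx, "cadmium", reference_scenario(),
                               seed = 4, n_mc = 2e4, warn_unmatched = FALSE)
  alt <- estimate_usual_intake(s, idx, "cadmium", only_pasta,
                               seed = 4, n_mc = 2e4, warn_unmatched = FALSE)
  expect_equal(alt$result$mean, ref$result$mean)
  expect_equal(alt$result$p95, ref$result$p95)
})

test_that("seaweed substitution raises iodine intake on synthetic data", {
  s <- simulate_survey(population_spec(n_individuals = 400, seed = 17))
  idx <- build_index(normalize_concentrations(synthetic_study_concentrations()))
  ref <- estimate_usual_intake(s, idx, "iodine", reference_scenario(),
                               seed = 4, n_mc = 2e4, warn_unmatched = FALSE)
  alt <- estimate_usual_intake(s, idx, "iodine", seaweed_scenario(),
                               seed = 4, n_mc = 2e4, warn_unmatched = FALSE)
  expect_gt(alt$result$mean, ref$result$mean)
})

test_that("the report bundle is deterministic and unit-consistent", {
  s <- simulate_survey(population_spec(n_individuals = 120, seed = 18))
  conc <- synthetic_study_concentrations()
  run <- function(dir) {
    run_pipeline(s, conc,
                 scenarios = list(reference_scenario(), seaweed_scenario()),
                 substances = c("iodine", "cadmium"), seed = 42, B = 25,
                 n_mc = 5000, out = dir)
  }
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- run(d1); b2 <- run(d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  # unit conventions carried through to the bundle
  expect_equal(unique(b1$results$unit[b1$results$substance == "iodine"]),
               "ug/day")
  expect_equal(unique(b1$results$unit[b1$results$substance == "cadmium"]),
               "ug/kg bw/day")
  # report values round-trip through the written table
  back <- read_result_table(file.path(d1, "results.tsv"))
  expect_equal(back$mean, b1$results$mean)
  expect_equal(back$p95_upper, b1$results$p95_upper)
  # every scenario x substance classified and logged
  expect_equal(nrow(b1$classification), 4L)
  expect_true(all(b1$classification$class %in%
                    c("green", "orange", "red", "unclassified")))
  expect_true(all(b1$log$censored_imputed > 0))
  # substitution happened only in the alternative scenario
  n_sub <- b1$log$records_substituted
  expect_true(all(n_sub[b1$log$scenario == "reference"] == 0))
  expect_true(all(n_sub[b1$log$scenario == "alternative"] > 0))
})
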