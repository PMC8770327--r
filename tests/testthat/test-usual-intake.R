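test_that("daily intakes follow the unit conventions exactly", {
  idx <- tiny_index()
  rec <- tibble::tibble(individual_id = "A", day_index = 1L,
                        food = "Algae>Seaweed pasta",
                        amount_cooked = 100, amount_raw = 100)
  s <- new_survey(tiny_individuals(), rec, n_days = 2)
  d <- compute_daily_intakes(s, idx, "t_arsenic", warn_unmatched = FALSE)
  # 0.1 kg x (40333/4.7) ug/kg / 70 kg bw
  expect_equal(d$value[d$individual_id == "A" & d$day_index == 1],
               (40333 / 4.7) * 0.1 / 70)
  # nutrient path uses cooked amounts and no body-weight division
  d2 <- compute_daily_intakes(s, idx, "iodine", warn_unmatched = FALSE)
  expect_equal(d2$value[d2$individual_id == "A" & d2$day_index == 1],
               29200 * 0.1)
  # empty person-days are present with value zero
  expect_equal(d$value[d$individual_id == "B"], c(0, 0))
})

test_that("contributions add across foods within a person-day", {
  idx <- tiny_index()
  rec <- tibble::tibble(individual_id = c("A", "A"), day_index = 1L,
                        food = c("Grains>Pasta", "Meat>Bacon"),
                        amount_cooked = c(100, 50), amount_raw = c(100, 50))
  s <- new_survey(tiny_individuals(), rec, n_days = 1)
  d <- compute_daily_intakes(s, idx, "cadmium", warn_unmatched = FALSE)
  expect_equal(d$value[d$individual_id == "A"],
               (0.1 * 14 + 0.05 * 7) / 70)
})

test_that("cooked and raw bases are routed to the right substance class", {
  idx <- tiny_index()
  rec <- tibble::tibble(individual_id = "A", day_index = 1L,
                        food = "Grains>Pasta",
                        amount_cooked = 100, amount_raw = 45)
  s <- new_survey(tiny_individuals(), rec, n_days = 1)
  iod <- compute_daily_intakes(s, idx, "iodine", warn_unmatched = FALSE)
  cad <- compute_daily_intakes(s, idx, "cadmium", warn_unmatched = FALSE)
  expect_equal(iod$value[iod$individual_id == "A"], 0.100 * 10)
  expect_equal(cad$value[cad$individual_id == "A"], 0.045 * 14 / 70)
})

test_that("the model fit handles degenerate inputs explicitly", {
  daily0 <- tibble::tibble(individual_id = rep(letters[1:5], each = 2),
                           day_index = rep(1:2, 5), value = 0)
  expect_error(fit_lnn(daily0), "all daily intakes are zero")

  daily1 <- tibble::tibble(individual_id = letters[1:5], day_index = 1L,
                           value = exp(rnorm(5)))
  expect_error(fit_lnn(daily1), "single recall day")

  # all-positive data: frequency degenerates to p = 1
  set.seed(1)
  dailyp <- tibble::tibble(individual_id = rep(sprintf("p%02d", 1:50), each = 2),
                           day_index = rep(1:2, 50),
                           value = exp(rnorm(100)))
  fit <- fit_lnn(dailyp)
  expect_true(fit$all_positive)
  expect_equal(fit$freq_sigma, 0)

  # no within-person variation: sigma_within estimates zero
  dailyc <- tibble::tibble(individual_id = rep(sprintf("p%02d", 1:50), each = 2),
                           day_index = rep(1:2, 50),
                           value = rep(exp(rnorm(50)), each = 2))
  expect_equal(fit_lnn(dailyc)$sigma_within, 0)
})

test_that("fit recovers generative parameters on balanced all-consumer data", {
  set.seed(2024)
  n <- 2000
  b <- rnorm(n, 0, 0.3)
  daily <- tibble::tibble(
    individual_id = rep(sprintf("i%04d", 1:n), each = 2),
    day_index = rep(1:2, n),
    value = exp(1 + rep(b, each = 2) + rnorm(2 * n, 0, 0.5))
  )
  fit <- fit_lnn(daily)
  expect_true(fit$all_positive)
  expect_lt(abs(fit$amount_mu - 1), 0.05)
  expect_lt(abs(fit$sigma_between / 0.3 - 1), 0.05)
  expect_lt(abs(fit$sigma_within / 0.5 - 1), 0.05)
})

test_that("frequency maximum likelihood recovers the logit-normal parameters", {
  set.seed(31)
  n <- 4000; D <- 4
  p <- stats::plogis(-0.5 + 0.8 * rnorm(n))
  k <- rbinom(n, D, p)
  daily <- tibble::tibble(
    individual_id = rep(seq_len(n), each = D),
    day_index = rep(seq_len(D), n),
    value = as.numeric(sequence(rep(D, n)) <= rep(k, each = D))
  )
  fit <- fit_lnn(daily)
  expect_lt(abs(fit$freq_mu - (-0.5)), 0.1)
  expect_lt(abs(fit$freq_sigma - 0.8), 0.1)
})

test_that("usual distribution collapses, shrinks and reproduces", {
  point <- structure(list(freq_mu = Inf, freq_sigma = 0, amount_mu = log(5),
                          sigma_between = 0, sigma_within = 0,
                          all_positive = TRUE), class = "lnn_fit")
  expect_equal(unique(usual_distribution(point, 2000, seed = 1)), 5)

  spec <- one_food_spec(n = 2000, seed = 41)
  s <- simulate_survey(spec)
  idx <- tiny_index()
  d <- compute_daily_intakes(s, idx, "iodine", warn_unmatched = FALSE)
  fit <- fit_lnn(d)
  u <- usual_distribution(fit, 5e4, seed = 2)
  # within-person day-to-day variance is averaged out of usual intake
  expect_lt(stats::var(u), stats::var(d$value))
  expect_lt(stats::quantile(d$value, 0.05), stats::quantile(u, 0.05))
  expect_gt(stats::quantile(d$value, 0.95), stats::quantile(u, 0.95))
  expect_identical(u, usual_distribution(fit, 5e4, seed = 2))
  expect_warning(usual_distribution(fit, 500, seed = 1), "n_mc")
})

test_that("usual-intake mean matches the weighted mean of daily intakes", {
  spec <- one_food_spec(n = 2000, seed = 51)
  s <- simulate_survey(spec)
  idx <- tiny_index()
  d <- compute_daily_intakes(s, idx, "iodine", warn_unmatched = FALSE)
  fit <- fit_lnn(d)
  u <- usual_distribution(fit, 2e5, seed = 3)
  expect_lt(abs(mean(u) / weighted_mean(d$value, d$sampling_weight) - 1), 0.02)
})

test_that("scaling concentrations scales every percentile exactly", {
  spec <- one_food_spec(n = 500, seed = 61)
  s <- simulate_survey(spec)
  norm <- normalize_concentrations(seaweed_concentrations())
  run <- function(nrm) {
    d <- compute_daily_intakes(s, build_index(nrm), "iodine",
                               warn_unmatched = FALSE)
    summarize_distribution(usual_distribution(fit_lnn(d), 2e4, seed = 5))
  }
  base <- run(norm)
  scaled <- run(dplyr::mutate(norm, value = 3 * .data$value))
  expect_equal(unlist(scaled), 3 * unlist(base), tolerance = 1e-12)
})

test_that("bootstrap intervals are reproducible and degenerate at B = 1", {
  spec <- one_food_spec(n = 300, seed = 71)
  s <- simulate_survey(spec)
  d <- compute_daily_intakes(s, tiny_index(), "iodine", warn_unmatched = FALSE)
  b1 <- bootstrap_usual_intake(d, B = 50, seed = 10, n_mc = 2000)
  b2 <- bootstrap_usual_intake(d, B = 50, seed = 10, n_mc = 2000)
  expect_identical(b1$stats, b2$stats)
  expect_warning(b3 <- bootstrap_usual_intake(d, B = 1, seed = 1, n_mc = 2000),
                 "degenerate")
  expect_equal(b3$stats$lower, b3$stats$upper)
})
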