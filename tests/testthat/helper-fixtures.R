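# small in-code fixtures shared across tests

tiny_individuals <- function() {
  tibble::tibble(
    id = c("A", "B"),
    sex = c("female", "male"),
    age = c(34, 61),
    body_weight = c(70, 85),
    sampling_weight = c(1, 1)
  )
}

tiny_survey <- function() {
  records <- tibble::tibble(
    individual_id = c("A", "A", "B"),
    day_index = c(1L, 2L, 1L),
    food = c("Grains>Pasta", "Meat>Bacon", "Grains>Pasta"),
    amount_cooked = c(100, 30, 150),
    amount_raw = c(45, 30, 67.5)
  )
  new_survey(tiny_individuals(), records, n_days = 2)
}

tiny_index <- function() {
  build_index(normalize_concentrations(seaweed_concentrations()))
}

# single-food population whose total intake follows one LNN process exactly,
# used wherever estimates are compared against the ground-truth oracle
one_food_spec <- function(n = 2000, seed = 11, freq_mu = -0.7,
                          freq_sigma = 1.0, amount_mu = log(60),
                          sb = 0.4, sw = 0.5) {
  population_spec(
    foods = tibble::tibble(food = "Algae>Seaweed pasta", freq_mu = freq_mu,
                           freq_sigma = freq_sigma, amount_mu = amount_mu,
                           amount_sigma_between = sb,
                           amount_sigma_within = sw, raw_yield = 1),
    n_individuals = n, seed = seed
  )
}

# mean of the logistic-normal consumption probability by numerical
# integration (independent oracle for the frequency part)
logit_normal_mean <- function(mu, sigma) {
  if (sigma == 0) return(stats::plogis(mu))
  stats::integrate(function(z) stats::plogis(mu + sigma * z) * stats::dnorm(z),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

write_tiny_survey_file <- function(path = tempfile(fileext = ".tsv")) {
  write_survey(tiny_survey(), path)
  path
}
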