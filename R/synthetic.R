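#' Population specification for the synthetic survey generator
#'
#' Defines a population with a known usual-intake structure, used to
#' validate the whole pipeline against ground truth. For each food the
#' generative model is the two-part logistic-normal-normal process the
#' estimator targets:
#'
#' * person-level consumption probability: `logit(p_i) ~ N(freq_mu, freq_sigma^2)`;
#' * consumption on each recall day: `Bernoulli(p_i)`, independent days;
#' * positive log amount: `log A_ij = amount_mu + b_i + e_ij`, with a
#'   between-person effect `b_i ~ N(0, amount_sigma_between^2)` and a
#'   within-person day residual `e_ij ~ N(0, amount_sigma_within^2)`.
#'
#' Frequency and amount effects are drawn independently (zero
#' frequency-amount correlation), matching the estimator's assumption.
#' Amounts are cooked grams per day; raw amounts are `cooked * raw_yield`.
#'
#' @param foods tibble with columns `food`, `freq_mu`, `freq_sigma` (logit
#'   scale), `amount_mu`, `amount_sigma_between`, `amount_sigma_within`
#'   (log-gram scale), `raw_yield`; defaults to [study_food_params()]
#' @param n_individuals number of participants
#' @param n_days recall days per participant (default 2)
#' @param bw_mean,bw_sd,bw_min body-weight distribution (kg), normal
#'   truncated below at `bw_min`
#' @param p_female probability of female sex
#' @param age_range uniform age range in years
#' @param weight_targets optional named numeric of target population
#'   fractions for the post-stratification strata `female_young`,
#'   `female_old`, `male_young`, `male_old` (young = below 50 y); `NULL`
#'   gives equal targets. Sampling weights are target/observed fraction,
#'   normalized to mean 1.
#' @param seed integer seed fixing all randomness of the generator
#' @return a `population_spec` object
#' @export
population_spec <- function(foods = study_food_params(),
                            n_individuals = 2000, n_days = 2,
                            bw_mean = 75, bw_sd = 14, bw_min = 40,
                            p_female = 0.5, age_range = c(19, 79),
                            weight_targets = NULL, seed = 1) {
  foods <- tibble::as_tibble(foods)
  need <- c("food", "freq_mu", "freq_sigma", "amount_mu",
            "amount_sigma_between", "amount_sigma_within")
  miss <- setdiff(need, names(foods))
  if (length(miss)) stop("foods table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"raw_yield" %in% names(foods)) foods$raw_yield <- 1
  stopifnot(all(foods$freq_sigma >= 0), all(foods$amount_sigma_between >= 0),
            all(foods$amount_sigma_within >= 0), all(foods$raw_yield > 0),
            n_days >= 1, n_individuals >= 1, bw_sd >= 0)
  validate_food_paths(foods$food)
  structure(list(foods = foods, n_individuals = as.integer(n_individuals),
                 n_days = as.integer(n_days), bw_mean = bw_mean,
                 bw_sd = bw_sd, bw_min = bw_min, p_female = p_female,
                 age_range = age_range, weight_targets = weight_targets,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Default multi-food parameters emulating an adult 2x24-h recall survey
#'
#' Five foods: the three substitution targets (pasta, bacon, rocket
#' lettuce) plus bread and sea fish as background diet. Frequencies and
#' amounts were set once so that population-mean consumption mirrors the
#' published summaries for Dutch adults (pasta about 26 g/day with roughly
#' a third of the population consuming, bacon about 3 g/day, lettuce about
#' 1.3 g/day); bread is a near-daily staple and fish an occasional food.
#' `raw_yield` converts cooked to raw grams (dried pasta swells when
#' cooked; the other foods are recorded at approximately equal mass).
#'
#' @return tibble of per-food generator parameters
#' @export
study_food_params <- function() {
  tibble::tribble(
    ~food,                               ~freq_mu, ~freq_sigma, ~amount_mu, ~amount_sigma_between, ~amount_sigma_within, ~raw_yield,
    "Grains>Bread",                      2.2,      1.0,         log(140),   0.30,                  0.35,                 1.00,
    "Grains>Pasta",                      -0.9,     1.3,         log(62),    0.45,                  0.55,                 0.45,
    "Meat>Bacon",                        -1.9,     1.2,         log(12),    0.55,                  0.65,                 1.00,
    "Vegetables>Lettuce>Rocket lettuce", -2.6,     1.0,         log(10),    0.50,                  0.60,                 1.00,
    "Fish>Sea fish",                     -1.4,     1.0,         log(110),   0.40,                  0.60,                 1.00
  )
}

# stratum labels used by the post-stratification weighting scheme
bw_stratum <- function(sex, age) {
  paste0(ifelse(sex == "female", "female_", "male_"),
         ifelse(age < 50, "young", "old"))
}

#' Simulate a recall survey from a population specification
#'
#' Draws the latent person-level frequency and amount effects, then the
#' day-level consumption indicators and amounts, for every (person, food)
#' pair. Deterministic given `spec$seed`.
#'
#' @param spec a [population_spec()]
#' @return a [new_survey()] object whose records contain only the
#'   person-days on which a food was actually consumed
#' @export
simulate_survey <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_individuals
    ids <- sprintf("P%05d", seq_len(n))
    sex <- ifelse(stats::runif(n) < spec$p_female, "female", "male")
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    bw <- stats::rnorm(n, spec$bw_mean, spec$bw_sd)
    while (any(bad <- bw < spec$bw_min)) {
      bw[bad] <- stats::rnorm(sum(bad), spec$bw_mean, spec$bw_sd)
    }
    strat <- bw_stratum(sex, age)
    targets <- spec$weight_targets %||%
      stats::setNames(rep(0.25, 4),
                      c("female_young", "female_old", "male_young", "male_old"))
    obs_frac <- table(factor(strat, levels = names(targets))) / n
    w <- unname(targets[strat] / pmax(as.numeric(obs_frac[strat]), 1e-12))
    w <- w / mean(w)
    individuals <- tibble::tibble(id = ids, sex = sex, age = age,
                                  body_weight = bw, sampling_weight = w)
    recs <- purrr::pmap(spec$foods, function(food, freq_mu, freq_sigma,
                                             amount_mu, amount_sigma_between,
                                             amount_sigma_within, raw_yield) {
      p <- stats::plogis(freq_mu + freq_sigma * stats::rnorm(n))
      b <- amount_sigma_between * stats::rnorm(n)
      out <- vector("list", spec$n_days)
      for (d in seq_len(spec$n_days)) {
        eats <- stats::runif(n) < p
        if (!any(eats)) next
        amt <- exp(amount_mu + b[eats] +
                     amount_sigma_within * stats::rnorm(sum(eats)))
        out[[d]] <- tibble::tibble(individual_id = ids[eats], day_index = d,
                                   food = food, amount_cooked = amt,
                                   amount_raw = amt * raw_yield)
      }
      dplyr::bind_rows(out)
    })
    records <- dplyr::bind_rows(recs) |>
      dplyr::arrange(.data$individual_id, .data$day_index, .data$food)
    new_survey(individuals, records, n_days = spec$n_days)
  })
}

#' Synthetic concentration table covering the default study foods
#'
#' Extends [seaweed_concentrations()] with synthetic background entries for
#' the two staple foods of [study_food_params()] (bread and sea fish), so
#' that every food in the default synthetic population carries occurrence
#' data for every substance. The background values are stand-ins of
#' realistic magnitude for European foods (iodized-salt bread as an iodine
#' and sodium source; marine fish as the dominant dietary source of total
#' arsenic), not measurements; they exist so end-to-end runs on synthetic
#' surveys exercise the full substance panel.
#'
#' @return tibble of concentration entries (see [read_concentrations()])
#' @export
synthetic_study_concentrations <- function() {
  background <- tibble::tribble(
    ~food,           ~substance,  ~value, ~unit,
    "Grains>Bread",  "iodine",    580,    "ug/kg",
    "Grains>Bread",  "sodium",    4000,   "mg/kg",
    "Grains>Bread",  "t_arsenic", 4,      "ug/kg",
    "Grains>Bread",  "i_arsenic", 4,      "ug/kg",
    "Grains>Bread",  "cadmium",   25,     "ug/kg",
    "Grains>Bread",  "lead",      12,     "ug/kg",
    "Grains>Bread",  "mercury",   1,      "ug/kg",
    "Fish>Sea fish", "iodine",    1200,   "ug/kg",
    "Fish>Sea fish", "sodium",    800,    "mg/kg",
    "Fish>Sea fish", "t_arsenic", 2500,   "ug/kg",
    "Fish>Sea fish", "i_arsenic", 30,     "ug/kg",
    "Fish>Sea fish", "cadmium",   10,     "ug/kg",
    "Fish>Sea fish", "lead",      15,     "ug/kg",
    "Fish>Sea fish", "mercury",   80,     "ug/kg"
  ) |>
    dplyr::mutate(basis = "wet", censoring = "measured",
                  censor_limit = NA_real_)
  dplyr::bind_rows(seaweed_concentrations(), background)
}

#' Ground-truth usual intake distribution of a synthetic population
#'
#' Monte-Carlo oracle for parameter-recovery tests: draws `n_mc`
#' individuals from the specification and computes each one's *true* usual
#' intake, i.e. the long-term expected daily intake given the person's
#' latent effects,
#' `UI_i = sum over foods of p_if * exp(amount_mu_f + b_if + sigma_w_f^2 / 2) * conc_f / 1000`,
#' with concentrations per kg and amounts in grams. Contaminant exposure is
#' divided by a body weight drawn from the spec's distribution. This is the
#' reference distribution the fitted estimator is compared against.
#'
#' @param spec a [population_spec()]
#' @param substance substance identifier
#' @param index a [build_index()] over normalized concentrations
#' @param n_mc Monte-Carlo sample size
#' @param seed seed for the oracle draw (defaults to `spec$seed + 1` so the
#'   oracle sample is independent of the simulated survey)
#' @return numeric vector of length `n_mc` (usual intake per individual)
#' @export
true_usual_intake_distribution <- function(spec, substance, index,
                                           n_mc = 1e5, seed = spec$seed + 1) {
  stopifnot(inherits(spec, "population_spec"))
  info <- substance_info(substance)
  conc <- lookup_concentration(index, spec$foods$food, substance,
                               warn_unmatched = FALSE)$value
  amount_col <- if (info$amount_basis == "raw") spec$foods$raw_yield else
    rep(1, nrow(spec$foods))
  withr::with_seed(as.integer(seed), {
    ui <- rep(0, n_mc)
    for (f in seq_len(nrow(spec$foods))) {
      if (conc[f] == 0) {
        # still need no draws: independence across foods keeps this exact
        next
      }
      fp <- spec$foods[f, ]
      p <- stats::plogis(fp$freq_mu + fp$freq_sigma * stats::rnorm(n_mc))
      b <- fp$amount_sigma_between * stats::rnorm(n_mc)
      usual_amt <- p * exp(fp$amount_mu + b + fp$amount_sigma_within^2 / 2) *
        amount_col[f]
      ui <- ui + usual_amt / 1000 * conc[f]
    }
    if (info$class == "contaminant") {
      bw <- stats::rnorm(n_mc, spec$bw_mean, spec$bw_sd)
      while (any(bad <- bw < spec$bw_min)) {
        bw[bad] <- stats::rnorm(sum(bad), spec$bw_mean, spec$bw_sd)
      }
      ui <- ui / bw
    }
    ui
  })
}
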