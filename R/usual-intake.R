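#' Assemble daily intakes of a substance from a survey
#'
#' For every person-day in the recall protocol (including days on which
#' none of the tracked foods was eaten, which contribute 0), sums
#' `amount_kg x concentration_per_kg` over the day's records. Cooked
#' amounts are used for nutrients and raw amounts for contaminants;
#' contaminant totals are divided by the individual's body weight, so the
#' returned values are in the substance's intake unit (ug/day, mg/day or
#' ug/kg bw/day, see [substance_registry()]). Concentrations come from the
#' hierarchical index with fallback ([lookup_concentration()]); foods with
#' no indexed ancestor contribute 0.
#'
#' @param survey a survey object
#' @param index a [build_index()] object (already wet-weight normalized)
#' @param substance substance identifier
#' @param warn_unmatched warn once about foods without concentration data
#' @return tibble with columns `individual_id`, `day_index`, `substance`,
#'   `value`, plus the person's `sampling_weight`
#' @export
compute_daily_intakes <- function(survey, index, substance,
                                  warn_unmatched = TRUE) {
  stopifnot(inherits(survey, "survey"))
  info <- substance_info(substance)
  ind <- survey$individuals
  if (info$class == "contaminant" && any(is.na(ind$body_weight))) {
    stop("body weight required for contaminant exposure", call. = FALSE)
  }
  rec <- survey$records
  grid <- tidyr::expand_grid(individual_id = ind$id,
                             day_index = seq_len(survey$n_days))
  if (nrow(rec)) {
    foods <- unique(rec$food)
    conc <- lookup_concentration(index, foods, substance,
                                 warn_unmatched = warn_unmatched)
    amount <- if (info$amount_basis == "raw") rec$amount_raw else rec$amount_cooked
    contrib <- tibble::tibble(
      individual_id = rec$individual_id,
      day_index = rec$day_index,
      value = amount / 1000 * conc$value[match(rec$food, conc$food)]
    ) |>
      dplyr::group_by(.data$individual_id, .data$day_index) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop")
  } else {
    contrib <- tibble::tibble(individual_id = character(),
                              day_index = integer(), value = double())
  }
  out <- grid |>
    dplyr::left_join(contrib, by = c("individual_id", "day_index")) |>
    dplyr::mutate(value = dplyr::coalesce(.data$value, 0),
                  substance = substance) |>
    dplyr::left_join(
      dplyr::select(ind, individual_id = "id", "sampling_weight",
                    "body_weight"),
      by = "individual_id"
    )
  if (info$class == "contaminant") {
    out$value <- out$value / out$body_weight
  }
  dplyr::select(out, "individual_id", "day_index", "substance", "value",
                "sampling_weight")
}

#' Fit the two-part logistic-normal-normal usual intake model
#'
#' Decomposes repeated daily intakes into a consumption-frequency part and
#' a positive-amount part, fitted independently (the frequency-amount
#' correlation is fixed at zero):
#'
#' * **Frequency**: each person's positive-day count is Bernoulli with a
#'   person-level probability whose logit is `N(freq_mu, freq_sigma^2)`.
#'   The marginal likelihood is integrated by Gauss-Hermite quadrature
#'   (`gh_nodes` nodes) and maximized numerically, with sampling weights
#'   as frequency weights. When every person-day is positive (total-diet
#'   nutrients and contaminants) the logistic stage degenerates to p = 1
#'   and is skipped.
#' * **Amount**: log positive amounts are decomposed into between-person
#'   (`sigma_between^2`) and within-person (`sigma_within^2`) variance by
#'   a weighted ANOVA-type moment estimator: the within component pools
#'   squared deviations from person means over persons with at least two
#'   positive days; the between component is the weighted variance of
#'   person means minus the expected within-person contribution, truncated
#'   at zero.
#'
#' @param daily tibble from [compute_daily_intakes()] (columns
#'   `individual_id`, `day_index`, `value`, optionally `sampling_weight`)
#' @param gh_nodes Gauss-Hermite nodes for the frequency likelihood
#' @return an `lnn_fit` with elements `freq_mu`, `freq_sigma` (logit
#'   scale; `Inf`/0 when degenerate at p = 1), `amount_mu`,
#'   `sigma_between`, `sigma_within` (log scale), `all_positive`,
#'   `n_individuals`, `convergence`
#' @export
fit_lnn <- function(daily, gh_nodes = 21) {
  stopifnot(all(c("individual_id", "day_index", "value") %in% names(daily)))
  if (!"sampling_weight" %in% names(daily)) daily$sampling_weight <- 1
  if (any(daily$value < 0)) stop("daily intakes must be >= 0", call. = FALSE)
  if (all(daily$value == 0)) {
    stop("degenerate fit: all daily intakes are zero", call. = FALSE)
  }
  # per-person sufficient statistics, vectorized (hot path of the bootstrap)
  f <- factor(daily$individual_id)
  n_days <- tabulate(f, nlevels(f))
  pos <- daily$value > 0
  k_pos <- as.vector(rowsum(as.numeric(pos), f, reorder = TRUE))
  w_all <- daily$sampling_weight[match(levels(f), daily$individual_id)]
  fp <- factor(daily$individual_id[pos], levels = levels(f))
  y <- log(daily$value[pos])
  # rowsum drops absent levels; scatter back onto the full person set
  rs <- rowsum(cbind(y, y^2), fp, reorder = TRUE)
  sum_y <- sum_y2 <- numeric(nlevels(f))
  hit <- match(rownames(rs), levels(f))
  sum_y[hit] <- rs[, 1]
  sum_y2[hit] <- rs[, 2]
  m_pos <- tabulate(fp, nlevels(f))
  ybar_all <- ifelse(m_pos > 0, sum_y / pmax(m_pos, 1L), NA_real_)
  ss_within_all <- pmax(sum_y2 - pmax(m_pos, 1L) * ybar_all^2, 0)
  per <- list(n_days = n_days, k_pos = k_pos, w = w_all,
              ybar = ybar_all, ss_within = ss_within_all)
  if (max(per$n_days) < 2L) {
    stop("within-person variance is unidentifiable with a single recall ",
         "day per person; at least part of the population needs >= 2 days",
         call. = FALSE)
  }

  all_positive <- all(per$k_pos == per$n_days)
  if (all_positive) {
    freq <- list(mu = Inf, sigma = 0, convergence = 0L)
  } else {
    freq <- fit_logit_normal(per$k_pos, per$n_days, per$w, gh_nodes)
  }

  cons <- per$k_pos >= 1L
  m <- per$k_pos[cons]
  w <- per$w[cons]
  ybar <- per$ybar[cons]
  ss_within <- per$ss_within[cons]
  with2 <- m >= 2L
  sigma_w2 <- if (any(with2)) {
    sum(w[with2] * ss_within[with2]) / sum(w[with2] * (m[with2] - 1L))
  } else 0
  amount_mu <- sum(w * ybar) / sum(w)
  # weighted variance of person means, with reliability-weight correction
  v1 <- sum(w); v2 <- sum(w^2)
  s2_means <- sum(w * (ybar - amount_mu)^2) / (v1 - v2 / v1)
  sigma_b2 <- max(0, s2_means - sigma_w2 * sum(w / m) / v1)

  structure(
    list(freq_mu = freq$mu, freq_sigma = freq$sigma,
         amount_mu = amount_mu, sigma_between = sqrt(sigma_b2),
         sigma_within = sqrt(sigma_w2), correlation = 0,
         all_positive = all_positive,
         n_individuals = length(per$n_days),
         n_consumers = sum(cons),
         convergence = freq$convergence, gh_nodes = gh_nodes),
    class = "lnn_fit"
  )
}

# ML for Bernoulli counts with a logit-normal person-level probability;
# the marginal likelihood is integrated with Gauss-Hermite quadrature.
fit_logit_normal <- function(k, n, w, gh_nodes = 21) {
  gh <- gh_rule(gh_nodes)
  # collapse to unique (k, n) patterns: likelihood cost is O(patterns)
  key <- factor(paste(k, n, sep = "/"))
  pw <- as.vector(rowsum(w, key, reorder = TRUE))
  kn <- do.call(rbind, strsplit(levels(key), "/", fixed = TRUE))
  pk <- as.numeric(kn[, 1]); pn <- as.numeric(kn[, 2])
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p <- stats::plogis(mu + sigma * gh$z)            # length G
    ll <- vapply(seq_along(pk), function(i) {
      log(sum(gh$w * p^pk[i] * (1 - p)^(pn[i] - pk[i])))
    }, numeric(1))
    -sum(pw * ll)
  }
  phat <- min(max(sum(w * k) / sum(w * n), 1e-4), 1 - 1e-4)
  fit <- stats::optim(c(stats::qlogis(phat), 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), convergence = fit$convergence)
}

#' @export
print.lnn_fit <- function(x, ...) {
  freq <- if (x$all_positive) "degenerate (p = 1)" else
    sprintf("logit-normal(mu = %.3f, sigma = %.3f)", x$freq_mu, x$freq_sigma)
  cat("<lnn_fit>\n",
      sprintf("  frequency: %s\n", freq),
      sprintf("  amount (log scale): mu = %.3f, sigma_between = %.3f, sigma_within = %.3f\n",
              x$amount_mu, x$sigma_between, x$sigma_within),
      sprintf("  %d individuals (%d consumers)\n", x$n_individuals,
              x$n_consumers), sep = "")
  invisible(x)
}

#' Monte-Carlo usual intake distribution from a fitted model
#'
#' Draws person-level frequency and amount effects independently from the
#' fitted normals and back-transforms to each simulated person's long-term
#' expected daily intake,
#' `UI_i = p_i * exp(amount_mu + b_i + sigma_within^2 / 2)`.
#' The within-person variance enters only through the log-normal mean
#' correction: day-to-day variation is averaged out of the usual intake.
#'
#' @param fit an [fit_lnn()] object
#' @param n_mc Monte-Carlo sample size (values below 1000 trigger a
#'   warning: percentile estimates get unstable)
#' @param seed integer seed; draws are reproducible
#' @return numeric vector of `n_mc` usual intakes
#' @export
usual_distribution <- function(fit, n_mc = 1e5, seed = 1) {
  stopifnot(inherits(fit, "lnn_fit"))
  if (n_mc < 1000) {
    warning("n_mc < 1000 gives unstable percentile estimates", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    p <- if (fit$all_positive) 1 else
      stats::plogis(fit$freq_mu + fit$freq_sigma * stats::rnorm(n_mc))
    b <- fit$sigma_between * stats::rnorm(n_mc)
    p * exp(fit$amount_mu + b + fit$sigma_within^2 / 2)
  })
}

#' Summarize a usual intake distribution
#'
#' @param dist numeric sample (from [usual_distribution()] or the oracle)
#' @param w optional weights
#' @return one-row tibble with `mean`, `p50`, `p75`, `p95`
#' @export
summarize_distribution <- function(dist, w = NULL) {
  q <- weighted_quantile(dist, w, c(0.5, 0.75, 0.95))
  tibble::tibble(mean = weighted_mean(dist, w),
                 p50 = q[[1]], p75 = q[[2]], p95 = q[[3]])
}

#' Bootstrap confidence intervals for usual intake statistics
#'
#' Resamples *individuals* (the clusters of the repeated-recall design)
#' with replacement, re-runs the LNN fit and the Monte-Carlo usual
#' distribution on each replicate, and returns percentile-method 2.5/97.5%
#' bounds for the mean and the reported percentiles. Replicates whose fit
#' fails are skipped; more than 20% failures is an error.
#'
#' @param daily tibble from [compute_daily_intakes()]
#' @param B number of bootstrap replicates (default 200; `B = 1` returns a
#'   degenerate interval with a warning)
#' @param seed integer seed driving resampling and replicate Monte-Carlo
#' @param n_mc Monte-Carlo size per replicate
#' @param gh_nodes passed to [fit_lnn()]
#' @param keep_samples keep each replicate's usual-intake sample (needed
#'   for bootstrap bounds on exceedance fractions)
#' @return list with `stats` (tibble: statistic, lower, upper),
#'   `replicates` (tibble of per-replicate mean/p50/p75/p95), `n_failed`,
#'   and `samples` (list of replicate samples) when `keep_samples = TRUE`
#' @export
bootstrap_usual_intake <- function(daily, B = 200, seed = 1, n_mc = 10000,
                                   gh_nodes = 21, keep_samples = FALSE) {
  stopifnot(B >= 1)
  if (B == 1) warning("B = 1: degenerate confidence interval", call. = FALSE)
  ids <- unique(daily$individual_id)
  n <- length(ids)
  by_id <- split(seq_len(nrow(daily)), daily$individual_id)
  reps <- withr::with_seed(as.integer(seed), {
    rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
    out <- vector("list", B)
    for (b in seq_len(B)) {
      take <- sample(ids, n, replace = TRUE)
      rows <- unlist(by_id[take], use.names = FALSE)
      # resampled persons must stay distinct clusters
      boot <- data.frame(
        individual_id = rep(seq_along(take), times = lengths(by_id[take])),
        day_index = daily$day_index[rows],
        value = daily$value[rows],
        sampling_weight = daily$sampling_weight[rows]
      )
      out[[b]] <- tryCatch({
        fit <- fit_lnn(boot, gh_nodes = gh_nodes)
        smp <- usual_distribution(fit, n_mc, seed = rep_seeds[b])
        list(stat = summarize_distribution(smp),
             sample = if (keep_samples) smp)
      }, error = function(e) NULL)
    }
    out
  })
  failed <- sum(vapply(reps, is.null, logical(1)))
  if (failed > 0.2 * B) {
    stop(sprintf("bootstrap failed in %d of %d replicates", failed, B),
         call. = FALSE)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  replicates <- dplyr::bind_rows(lapply(reps, `[[`, "stat"))
  stats_tbl <- tidyr::pivot_longer(replicates, dplyr::everything(),
                                   names_to = "statistic") |>
    dplyr::group_by(.data$statistic) |>
    dplyr::summarise(
      lower = unname(stats::quantile(.data$value, 0.025, type = 7)),
      upper = unname(stats::quantile(.data$value, 0.975, type = 7)),
      .groups = "drop"
    )
  list(stats = stats_tbl, replicates = replicates, n_failed = failed,
       samples = if (keep_samples) lapply(reps, `[[`, "sample"))
}

#' Estimate the usual intake of one substance under one scenario
#'
#' Convenience wrapper chaining [apply_scenario()],
#' [compute_daily_intakes()], [fit_lnn()], [usual_distribution()] and
#' (optionally) [bootstrap_usual_intake()] into a single result row of the
#' kind the reporting layer tabulates.
#'
#' @param survey a survey object
#' @param index a [build_index()] object
#' @param substance substance identifier
#' @param scn a [scenario()]; default [reference_scenario()]
#' @param seed integer seed
#' @param n_mc Monte-Carlo size for the usual distribution
#' @param B bootstrap replicates; `B = 0` skips interval estimation
#' @param gh_nodes passed to [fit_lnn()]
#' @param keep_samples passed to [bootstrap_usual_intake()]
#' @param warn_unmatched passed to [compute_daily_intakes()]
#' @return list with `result` (one-row tibble: substance, scenario, unit,
#'   mean + CI, p50, p75, p95 + CI), `fit`, `dist`, `daily`, `bootstrap`
#' @export
estimate_usual_intake <- function(survey, index, substance,
                                  scn = reference_scenario(), seed = 1,
                                  n_mc = 1e5, B = 0, gh_nodes = 21,
                                  keep_samples = FALSE, warn_unmatched = TRUE) {
  info <- substance_info(substance)
  sub_survey <- apply_scenario(survey, scn)
  daily <- compute_daily_intakes(sub_survey, index, substance,
                                 warn_unmatched = warn_unmatched)
  fit <- fit_lnn(daily, gh_nodes = gh_nodes)
  dist <- usual_distribution(fit, n_mc = n_mc, seed = seed)
  est <- summarize_distribution(dist)
  boot <- NULL
  lo <- hi <- p95_lo <- p95_hi <- NA_real_
  if (B >= 1) {
    boot <- bootstrap_usual_intake(daily, B = B, seed = seed + 1L,
                                   gh_nodes = gh_nodes,
                                   keep_samples = keep_samples)
    ci <- function(stat, side) {
      boot$stats[[side]][boot$stats$statistic == stat]
    }
    lo <- ci("mean", "lower"); hi <- ci("mean", "upper")
    p95_lo <- ci("p95", "lower"); p95_hi <- ci("p95", "upper")
  }
  result <- tibble::tibble(
    substance = substance, scenario = scn$name, unit = info$intake_unit,
    mean = est$mean, mean_lower = lo, mean_upper = hi,
    p50 = est$p50, p75 = est$p75,
    p95 = est$p95, p95_lower = p95_lo, p95_upper = p95_hi
  )
  list(result = result, fit = fit, dist = dist, daily = daily,
       bootstrap = boot)
}
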