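#' Health-based guidance value registry
#'
#' Loads the packaged registry of guidance values (adequate intake and
#' upper level for iodine, safe-and-adequate intake for sodium,
#' provisional tolerable weekly/monthly intakes for cadmium and mercury)
#' and benchmark-dose reference points (inorganic arsenic, lead) set by
#' EFSA and JECFA. Weekly and monthly values are kept in their original
#' period; convert with [to_daily()] before comparing with daily exposure.
#'
#' @param path optional alternative YAML registry with the same structure
#' @return tibble with one row per reference: `substance`, `species`,
#'   `authority`, `ref_type`, `label`, `value`, `value_upper`, `period`,
#'   `unit`, `concern`, `critical_effect`
#' @export
health_references <- function(path = NULL) {
  path <- path %||% system.file("extdata", "health_references.yaml",
                                package = "rbfood", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  purrr::map_dfr(cfg$references, function(r) {
    tibble::tibble(
      substance = r$substance,
      species = r$species %||% NA_character_,
      authority = r$authority,
      ref_type = r$ref_type,
      label = r$label %||% r$ref_type,
      value = as.double(r$value),
      value_upper = as.double(r$value_upper %||% NA),
      period = r$period,
      unit = r$unit,
      concern = r$concern,
      critical_effect = r$critical_effect %||% NA_character_
    )
  })
}

#' Recalculate guidance values to a daily basis
#'
#' Weekly values are divided by 7 and monthly values by 30 (a month is
#' taken as 30 days); daily values pass through unchanged. Full precision
#' is kept in `value_daily`; `value_daily_reported` rounds half away from
#' zero to 2 decimals, the precision at which daily-recalculated tolerable
#' intakes are conventionally quoted (2.5/7 -> 0.36, 25/30 -> 0.83).
#'
#' @param refs tibble from [health_references()] (or a subset)
#' @return the tibble with added `value_daily`, `value_upper_daily`,
#'   `value_daily_reported` columns and `period` set to `"day"`
#' @export
to_daily <- function(refs) {
  div <- unname(c(day = 1, week = 7, month = 30)[refs$period])
  if (anyNA(div)) {
    stop("unknown period(s): ",
         paste(unique(refs$period[is.na(div)]), collapse = ", "),
         " (expected day/week/month)", call. = FALSE)
  }
  refs$value_daily <- refs$value / div
  refs$value_upper_daily <- refs$value_upper / div
  refs$value_daily_reported <- round_half_up(refs$value_daily, 2)
  refs$period <- "day"
  refs
}

#' Margin of exposure against a benchmark-dose reference point
#'
#' The MoE is the reference point divided by the estimated exposure (both
#' in ug/kg bw/day). For a BMDL range both bounds are divided, giving a
#' (lower, upper) MoE pair. Values near or below 1 indicate exposure at
#' the level of the reference point.
#'
#' @param ref one-row tibble from [to_daily()] with a BMDL `ref_type`
#' @param exposure estimated exposure (ug/kg bw/day); 0 gives an infinite
#'   MoE, flagged with a warning
#' @return named numeric: `moe`, or `moe_lower`/`moe_upper` for a range
#' @export
margin_of_exposure <- function(ref, exposure) {
  stopifnot(nrow(ref) == 1L, exposure >= 0)
  if (!grepl("^BMDL", ref$ref_type)) {
    stop("margin of exposure is defined against BMDL reference points",
         call. = FALSE)
  }
  if (ref$period != "day") stop("convert the reference with to_daily() first",
                                call. = FALSE)
  if (exposure == 0) {
    warning("zero exposure: margin of exposure is infinite", call. = FALSE)
  }
  if (ref$ref_type == "BMDL_range") {
    c(moe_lower = ref$value_daily / exposure,
      moe_upper = ref$value_upper_daily / exposure)
  } else {
    c(moe = ref$value_daily / exposure)
  }
}

#' Fraction of the population beyond a guidance value
#'
#' Weighted fraction of a usual-intake sample above (or below) a
#' daily-basis threshold, with optional bootstrap bounds computed by
#' applying the same fraction to each replicate sample.
#'
#' @param dist numeric usual-intake sample
#' @param threshold daily-basis guidance value or reference point
#' @param direction `"above"` (exceedance) or `"below"` (compliance)
#' @param w optional weights for `dist`
#' @param replicates optional list of replicate samples (e.g. from a
#'   bootstrap with `keep_samples = TRUE`) for lower/upper bounds
#' @return one-row tibble: `fraction`, `lower`, `upper`
#' @export
exceedance_fraction <- function(dist, threshold, direction = c("above", "below"),
                                w = NULL, replicates = NULL) {
  direction <- match.arg(direction)
  frac_of <- function(x) {
    ind <- if (direction == "above") x > threshold else x < threshold
    weighted_mean(as.numeric(ind), if (identical(x, dist)) w else NULL)
  }
  fraction <- frac_of(dist)
  lo <- hi <- NA_real_
  if (!is.null(replicates) && length(replicates)) {
    fr <- vapply(replicates, frac_of, numeric(1))
    lo <- unname(stats::quantile(fr, 0.025, type = 7))
    hi <- unname(stats::quantile(fr, 0.975, type = 7))
  }
  tibble::tibble(fraction = fraction, lower = lo, upper = hi)
}

# references applicable to a substance, honouring the precautionary
# speciation mapping: total mercury is compared against the methyl-mercury
# PTWI and total arsenic against the inorganic-arsenic reference points.
applicable_references <- function(substance, refs, precautionary = TRUE) {
  if (substance == "mercury") {
    species <- if (precautionary) "methyl" else "inorganic"
    return(refs[refs$substance == "mercury" & refs$species %in% species, ])
  }
  if (substance == "t_arsenic" && precautionary) {
    return(refs[refs$substance == "i_arsenic", ])
  }
  refs[refs$substance == substance, ]
}

#' Traffic-light classification of a usual intake result
#'
#' Applies the documented coloring rule to a result row (see
#' [estimate_usual_intake()]): against the most conservative daily "excess"
#' reference for the substance (the minimum across authorities, using the
#' lower bound of a BMDL range), the class is **red** when the population
#' mean already breaches it, **orange** ("at risk") when the mean complies
#' but the 95th percentile breaches, and **green** otherwise. For
#' references guarding against deficit (adequate intake), the median below
#' the reference gives red. Substances without a registered reference are
#' `"unclassified"`.
#'
#' @param result one-row tibble with `substance`, `mean`, `p50`, `p95`
#' @param refs registry tibble from [health_references()]
#' @param precautionary compare total mercury/arsenic against the
#'   speciated (methyl-mercury / inorganic-arsenic) references
#' @return one-row tibble: `substance`, `class`, `basis`, `reference`,
#'   `reference_value` (daily basis)
#' @export
classify_result <- function(result, refs = health_references(),
                            precautionary = TRUE) {
  stopifnot(nrow(result) == 1L)
  sub <- applicable_references(result$substance, refs, precautionary)
  if (nrow(sub) == 0L) {
    return(tibble::tibble(substance = result$substance,
                          class = "unclassified", basis = NA_character_,
                          reference = NA_character_,
                          reference_value = NA_real_))
  }
  sub <- to_daily(sub)
  excess <- sub[sub$concern == "excess", ]
  deficit <- sub[sub$concern == "deficit", ]
  cls <- "green"; basis <- "mean and P95 within all references"
  ref_lab <- NA_character_; ref_val <- NA_real_
  if (nrow(excess)) {
    i <- which.min(excess$value_daily)
    lim <- excess$value_daily[i]
    ref_lab <- sprintf("%s %s (%s)", excess$authority[i], excess$label[i],
                       excess$substance[i])
    ref_val <- lim
    if (result$mean > lim) {
      cls <- "red"; basis <- "mean exceeds reference"
    } else if (result$p95 > lim) {
      cls <- "orange"; basis <- "P95 exceeds reference (at risk)"
    }
  }
  if (cls == "green" && nrow(deficit)) {
    j <- which.max(deficit$value_daily)
    if (result$p50 < deficit$value_daily[j]) {
      cls <- "red"; basis <- "median below adequate intake"
      ref_lab <- sprintf("%s %s (%s)", deficit$authority[j],
                         deficit$label[j], deficit$substance[j])
      ref_val <- deficit$value_daily[j]
    }
  }
  tibble::tibble(substance = result$substance, class = cls, basis = basis,
                 reference = ref_lab, reference_value = ref_val)
}
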