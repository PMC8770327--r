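#' Top contributing foods to a substance's intake
#'
#' Ranks foods by their weighted population-mean daily contribution
#' (substance units per day, contaminants per kg body weight): for each
#' food, the mean over all person-days of `amount_kg x concentration`,
#' weighted by sampling weight. Shares are contributions divided by the
#' total population mean and sum to 1; ties in the ranking are broken
#' lexicographically by food path.
#'
#' @param survey a survey object (after any scenario substitution)
#' @param index a [build_index()] object
#' @param substance substance identifier
#' @param top_k number of rows to return (default all foods)
#' @return tibble with `rank`, `food`, `substance`, `mean_contribution`,
#'   `share`
#' @export
contributors <- function(survey, index, substance, top_k = Inf) {
  info <- substance_info(substance)
  rec <- survey$records
  if (nrow(rec) == 0L) {
    return(tibble::tibble(rank = integer(), food = character(),
                          substance = character(),
                          mean_contribution = double(), share = double()))
  }
  conc <- lookup_concentration(index, unique(rec$food), substance,
                               warn_unmatched = FALSE)
  ind <- survey$individuals
  w <- stats::setNames(ind$sampling_weight, ind$id)
  bw <- stats::setNames(ind$body_weight, ind$id)
  amount <- if (info$amount_basis == "raw") rec$amount_raw else rec$amount_cooked
  contrib <- amount / 1000 * conc$value[match(rec$food, conc$food)]
  if (info$class == "contaminant") contrib <- contrib / bw[rec$individual_id]
  # weighted mean per day across the whole population (person-days)
  denom <- sum(w) * survey$n_days
  by_food <- tibble::tibble(food = rec$food,
                            wc = contrib * w[rec$individual_id]) |>
    dplyr::group_by(.data$food) |>
    dplyr::summarise(mean_contribution = sum(.data$wc) / denom,
                     .groups = "drop")
  total <- sum(by_food$mean_contribution)
  out <- by_food |>
    dplyr::mutate(share = if (total > 0) .data$mean_contribution / total else 0,
                  substance = substance) |>
    dplyr::arrange(dplyr::desc(.data$mean_contribution), .data$food) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::select("rank", "food", "substance", "mean_contribution", "share")
  utils::head(out, top_k)
}

#' Write / read a usual-intake result table
#'
#' One row per substance x scenario with the mean, P50, P75 and P95 and
#' the 95% confidence intervals for the mean and P95, in the layout of
#' standard exposure-assessment reports. Numbers round-trip losslessly at
#' full double precision.
#'
#' @param results tibble of result rows (see [estimate_usual_intake()])
#' @param path output path (`.csv` comma, else tab)
#' @return `write_result_table()` returns `path` invisibly;
#'   `read_result_table()` returns the tibble.
#' @export
write_result_table <- function(results, path) {
  cols <- c("substance", "scenario", "unit", "mean", "mean_lower",
            "mean_upper", "p50", "p75", "p95", "p95_lower", "p95_upper")
  miss <- setdiff(cols, names(results))
  if (length(miss)) stop("results table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  out <- results[cols]
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Run the full risk-benefit assessment pipeline
#'
#' End-to-end orchestration: normalizes and indexes the concentration
#' table, then for every scenario x substance estimates the usual intake
#' distribution (with bootstrap CIs when `B > 0`), classifies it against
#' the guidance-value registry, computes margins of exposure for
#' BMDL-bearing substances, exceedance fractions for every applicable
#' daily reference, and the top contributing foods. Fully reproducible
#' given `seed`.
#'
#' @param survey a survey object (or path readable by [read_survey()])
#' @param concentrations concentration entries (or a file path)
#' @param scenarios list of [scenario()] objects
#' @param substances character vector of substances to assess
#' @param refs guidance registry from [health_references()]
#' @param policy a [conversion_policy()]
#' @param seed integer master seed
#' @param B bootstrap replicates per substance x scenario (0 = none)
#' @param n_mc Monte-Carlo size for usual distributions
#' @param top_k contributor rows per substance x scenario
#' @param precautionary speciation mapping flag, see [classify_result()]
#' @param out optional output directory; when given, writes
#'   `report.json`, `results.tsv`, `classification.tsv`,
#'   `contributors.tsv`
#' @return a report bundle: list with tibbles `results`,
#'   `classification`, `moe`, `exceedance`, `contributors`, and `log`
#'   (stage counts: records substituted, foods unmatched, censored
#'   entries imputed)
#' @export
run_pipeline <- function(survey, concentrations, scenarios = list(reference_scenario()),
                         substances = substance_registry()$substance,
                         refs = health_references(),
                         policy = conversion_policy(), seed = 1, B = 0,
                         n_mc = 1e5, top_k = 5, precautionary = TRUE,
                         out = NULL) {
  if (is.character(survey)) survey <- read_survey(survey)
  if (is.character(concentrations)) {
    concentrations <- read_concentrations(concentrations)
  }
  normalized <- normalize_concentrations(concentrations, policy)
  index <- build_index(normalized)
  n_imputed <- sum(grepl("^imputed", normalized$provenance))

  refs_daily <- to_daily(refs)
  results <- list(); classification <- list(); moes <- list()
  exceed <- list(); contribs <- list(); logs <- list()
  for (scn in scenarios) {
    sub_survey <- apply_scenario(survey, scn)
    n_subst <- nrow(sub_survey$records) - nrow(survey$records)
    for (substance in substances) {
      est <- estimate_usual_intake(sub_survey, index, substance,
                                   scn = reference_scenario(),
                                   seed = seed, n_mc = n_mc, B = B,
                                   keep_samples = TRUE,
                                   warn_unmatched = FALSE)
      est$result$scenario <- scn$name
      key <- paste(scn$name, substance, sep = ".")
      results[[key]] <- est$result
      classification[[key]] <- dplyr::mutate(
        classify_result(est$result, refs, precautionary),
        scenario = scn$name, .after = "substance")

      app <- to_daily(applicable_references(substance, refs, precautionary))
      bmdl <- app[grepl("^BMDL", app$ref_type), ]
      if (nrow(bmdl) && est$result$mean > 0) {
        moes[[key]] <- purrr::map_dfr(seq_len(nrow(bmdl)), function(i) {
          m <- margin_of_exposure(bmdl[i, ], est$result$mean)
          tibble::tibble(substance = substance, scenario = scn$name,
                         reference = sprintf("%s %s", bmdl$authority[i],
                                             bmdl$label[i]),
                         moe_lower = m[[1]],
                         moe_upper = m[[length(m)]])
        })
      }
      boot_samples <- if (!is.null(est$bootstrap)) est$bootstrap$samples
      if (nrow(app)) {
        exceed[[key]] <- purrr::map_dfr(seq_len(nrow(app)), function(i) {
          direction <- if (app$concern[i] == "deficit") "below" else "above"
          ef <- exceedance_fraction(est$dist, app$value_daily[i], direction,
                                    replicates = boot_samples)
          dplyr::mutate(ef, substance = substance, scenario = scn$name,
                        reference = sprintf("%s %s", app$authority[i],
                                            app$label[i]),
                        threshold = app$value_daily[i],
                        direction = direction, .before = 1)
        })
      }
      contribs[[key]] <- dplyr::mutate(
        contributors(sub_survey, index, substance, top_k),
        scenario = scn$name, .after = "substance")
      n_unmatched <- sum(lookup_concentration(
        index, unique(sub_survey$records$food), substance,
        warn_unmatched = FALSE)$provenance == "unmatched")
      logs[[key]] <- tibble::tibble(
        scenario = scn$name, substance = substance,
        records_substituted = n_subst, foods_unmatched = n_unmatched,
        censored_imputed = n_imputed)
    }
  }
  bundle <- list(results = dplyr::bind_rows(results),
                 classification = dplyr::bind_rows(classification),
                 moe = dplyr::bind_rows(moes),
                 exceedance = dplyr::bind_rows(exceed),
                 contributors = dplyr::bind_rows(contribs),
                 log = dplyr::bind_rows(logs))
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(bundle, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_result_table(bundle$results, file.path(out, "results.tsv"))
    readr::write_tsv(bundle$classification,
                     file.path(out, "classification.tsv"), progress = FALSE)
    readr::write_tsv(bundle$contributors,
                     file.path(out, "contributors.tsv"), progress = FALSE)
  }
  bundle
}
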