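#' Dietary survey container
#'
#' A `survey` bundles the two tables of a short-term recall study:
#'
#' * `individuals`: one row per participant with `id`, `sex`, `age` (years),
#'   `body_weight` (kg) and a non-negative `sampling_weight` (default 1)
#'   used as a frequency weight in estimation;
#' * `records`: one row per food eaten by one person on one recall day,
#'   with `individual_id`, `day_index` (1..n_days), `food` (serialized
#'   hierarchy path) and the consumed mass in grams per day on both the
#'   cooked (`amount_cooked`) and raw (`amount_raw`) basis. Cooked amounts
#'   feed nutrient intake, raw amounts contaminant exposure.
#'
#' A person with no records on a given day simply ate none of the tracked
#' foods that day; the number of recall days each participant completed is
#' carried as `n_days`.
#'
#' @param individuals data frame as described above
#' @param records data frame as described above
#' @param n_days number of recall days in the protocol; defaults to the
#'   largest `day_index` observed
#' @return an object of class `survey`
#' @seealso [read_survey()], [simulate_survey()]
#' @export
new_survey <- function(individuals, records, n_days = NULL) {
  individuals <- tibble::as_tibble(individuals)
  records <- tibble::as_tibble(records)
  if (is.null(n_days)) {
    n_days <- if (nrow(records)) max(records$day_index) else 1L
  }
  out <- structure(
    list(individuals = individuals, records = records,
         n_days = as.integer(n_days)),
    class = "survey"
  )
  validate_survey(out)
}

#' @export
print.survey <- function(x, ...) {
  cat(sprintf("<survey> %d individuals, %d consumption records, %d recall day(s)\n",
              nrow(x$individuals), nrow(x$records), x$n_days))
  invisible(x)
}

#' Validate a survey object
#'
#' Checks the structural invariants: required columns, positive body
#' weights, non-negative sampling weights and amounts, day indices within
#' the protocol, and every record referencing a known individual.
#'
#' @param survey a [new_survey()] object
#' @return the survey, invisibly-validated (errors on violation)
#' @export
validate_survey <- function(survey) {
  ind <- survey$individuals
  rec <- survey$records
  need_ind <- c("id", "sex", "age", "body_weight", "sampling_weight")
  need_rec <- c("individual_id", "day_index", "food", "amount_cooked", "amount_raw")
  miss <- setdiff(need_ind, names(ind))
  if (length(miss)) stop("individuals table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(need_rec, names(rec))
  if (length(miss)) stop("records table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ind$id)) stop("duplicate individual ids", call. = FALSE)
  if (any(ind$body_weight <= 0 | is.na(ind$body_weight)))
    stop("body_weight must be > 0 for every individual", call. = FALSE)
  if (any(ind$sampling_weight < 0 | is.na(ind$sampling_weight)))
    stop("sampling_weight must be >= 0", call. = FALSE)
  if (nrow(rec)) {
    validate_food_paths(rec$food)
    bad_amt <- which(rec$amount_cooked < 0 | rec$amount_raw < 0)
    if (length(bad_amt)) {
      stop(sprintf("negative consumption amount in record row(s) %s",
                   paste(utils::head(bad_amt, 5), collapse = ", ")), call. = FALSE)
    }
    if (any(rec$day_index < 1 | rec$day_index > survey$n_days))
      stop("day_index outside 1..n_days", call. = FALSE)
    unknown <- setdiff(unique(rec$individual_id), ind$id)
    if (length(unknown)) {
      stop("records reference unknown individual(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  survey
}

#' Read a survey from a delimited file
#'
#' Expects one flat table with a header, one row per consumption record,
#' carrying the participant attributes alongside each record. Required
#' columns: `individual_id`, `sex`, `age`, `body_weight`, `day_index`,
#' `food`, `amount_cooked`, `amount_raw`; `sampling_weight` is optional and
#' defaults to 1. The individuals table is rebuilt from the distinct
#' participant attributes.
#'
#' @param path file path
#' @param delim field delimiter; `NULL` guesses from the extension
#'   (`.csv` -> comma, otherwise tab)
#' @param n_days recall days in the protocol; default observed maximum
#' @return a [new_survey()] object
#' @export
read_survey <- function(path, delim = NULL, n_days = NULL) {
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("individual_id", "sex", "age", "body_weight", "day_index",
            "food", "amount_cooked", "amount_raw")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("survey file %s missing required column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"sampling_weight" %in% names(df)) df$sampling_weight <- 1
  bad <- which(df$amount_cooked < 0 | df$amount_raw < 0)
  if (length(bad)) {
    stop(sprintf("negative amount in row(s) %s of %s",
                 paste(bad, collapse = ", "), path), call. = FALSE)
  }
  individuals <- dplyr::distinct(
    df, id = .data$individual_id, sex = .data$sex, age = .data$age,
    body_weight = .data$body_weight, sampling_weight = .data$sampling_weight
  )
  if (anyDuplicated(individuals$id)) {
    stop("inconsistent individual attributes across rows for the same id",
         call. = FALSE)
  }
  records <- dplyr::select(df, "individual_id", "day_index", "food",
                           "amount_cooked", "amount_raw")
  new_survey(individuals, records, n_days = n_days)
}

#' Write a survey to a delimited file
#'
#' Inverse of [read_survey()]: one flat row per consumption record with the
#' participant attributes joined in.
#'
#' @param survey a survey object
#' @param path output file path (`.csv` for comma, else tab)
#' @return `path`, invisibly
#' @export
write_survey <- function(survey, path) {
  flat <- survey$records |>
    dplyr::left_join(
      dplyr::rename(survey$individuals, individual_id = "id"),
      by = "individual_id"
    ) |>
    dplyr::select("individual_id", "sex", "age", "body_weight",
                  "sampling_weight", "day_index", "food",
                  "amount_cooked", "amount_raw")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(flat, path, progress = FALSE)
  } else {
    readr::write_tsv(flat, path, progress = FALSE)
  }
  invisible(path)
}
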