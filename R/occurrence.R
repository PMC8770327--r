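#' Conversion policy for occurrence data
#'
#' Bundles the two constants applied when normalizing a concentration
#' table: the dry-to-wet weight conversion factor (default 4.7, reflecting
#' the water content of fresh kelp relative to the dried product) and the
#' fraction of the LOD/LOQ assigned to left-censored measurements (default
#' 0.5, the middle-bound treatment; 0 and 1 give lower-/upper-bound
#' sensitivity runs).
#'
#' @param dw_to_ww_factor positive dry-to-wet conversion factor
#' @param censored_fraction fraction of the censoring limit assigned to
#'   non-detects, in \[0, 1\]
#' @return a `conversion_policy` list
#' @export
conversion_policy <- function(dw_to_ww_factor = 4.7, censored_fraction = 0.5) {
  stopifnot(is.numeric(dw_to_ww_factor), dw_to_ww_factor > 0,
            is.numeric(censored_fraction),
            censored_fraction >= 0, censored_fraction <= 1)
  structure(list(dw_to_ww_factor = dw_to_ww_factor,
                 censored_fraction = censored_fraction),
            class = "conversion_policy")
}

#' Resolve left-censored concentration values
#'
#' Measured values pass through unchanged; values below the limit of
#' detection or quantification are imputed at
#' `censored_fraction * censor_limit` (one half by default).
#'
#' @param value numeric measured values (ignored where censored)
#' @param censoring `measured`, `below_LOD` or `below_LOQ`
#' @param censor_limit the LOD/LOQ for censored entries
#' @param policy a [conversion_policy()]
#' @return numeric vector of resolved concentrations
#' @export
resolve_censored <- function(value, censoring, censor_limit,
                             policy = conversion_policy()) {
  censoring <- recode_censoring(censoring)
  cens <- censoring != "measured"
  if (any(cens & (is.na(censor_limit) | censor_limit <= 0))) {
    stop("censored entry without a positive censor_limit", call. = FALSE)
  }
  ifelse(cens, policy$censored_fraction * censor_limit, value)
}

#' Convert a dry-weight concentration to wet weight
#'
#' Divides by the policy's conversion factor. Full precision is kept; use
#' [round_half_up()] only when reproducing printed table values.
#'
#' @param value_dw concentration per kg dry weight (non-negative)
#' @param policy a [conversion_policy()]
#' @return concentration per kg wet weight
#' @examples
#' dw_to_ww(40333)                 # 8581.49...
#' round_half_up(dw_to_ww(40333))  # 8582, as printed
#' @export
dw_to_ww <- function(value_dw, policy = conversion_policy()) {
  stopifnot(all(value_dw >= 0, na.rm = TRUE))
  value_dw / policy$dw_to_ww_factor
}

#' Normalize a concentration table to resolved wet-weight values
#'
#' Applies [resolve_censored()] and [dw_to_ww()] so that every entry is a
#' directly usable wet-weight concentration. The returned table keeps one
#' row per (food, substance) with the resolved `value` and a `provenance`
#' note (`measured`, `imputed_half_LOD`, `imputed_half_LOQ`,
#' `converted_dw`).
#'
#' @param entries tibble from [read_concentrations()]
#' @param policy a [conversion_policy()]
#' @return tibble with columns `food`, `substance`, `value`, `unit`,
#'   `provenance`
#' @export
normalize_concentrations <- function(entries, policy = conversion_policy()) {
  entries <- validate_concentrations(entries)
  value <- resolve_censored(entries$value, entries$censoring,
                            entries$censor_limit, policy)
  dry <- entries$basis == "dry"
  value[dry] <- dw_to_ww(value[dry], policy)
  provenance <- dplyr::case_when(
    entries$censoring == "below_LOD" ~ "imputed_half_LOD",
    entries$censoring == "below_LOQ" ~ "imputed_half_LOQ",
    dry ~ "converted_dw",
    TRUE ~ "measured"
  )
  tibble::tibble(food = entries$food, substance = entries$substance,
                 value = value, unit = entries$unit, provenance = provenance)
}

#' Build a hierarchical concentration index
#'
#' Indexes normalized (wet-weight, censoring-resolved) concentrations by
#' food path and, at every broader hierarchy level, stores the unweighted
#' arithmetic mean of the indexed entries beneath it. Lookups can then fall
#' back from a specific food to the deepest ancestor that carries data,
#' mirroring the way aggregated occurrence means are ascribed at broader
#' classification levels when food-specific measurements are missing.
#'
#' @param normalized tibble from [normalize_concentrations()]
#' @param delim path delimiter
#' @return a `concentration_index` object
#' @export
build_index <- function(normalized, delim = ">") {
  need <- c("food", "substance", "value")
  miss <- setdiff(need, names(normalized))
  if (length(miss)) stop("normalized table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  dup <- normalized |>
    dplyr::count(.data$substance, .data$food) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicate (food, substance) entries: ",
         paste(paste(dup$substance, dup$food, sep = " / "), collapse = "; "),
         call. = FALSE)
  }
  nodes <- normalized |>
    dplyr::mutate(
      node = purrr::map(.data$food, food_ancestors, delim = delim)
    ) |>
    tidyr::unnest("node") |>
    dplyr::group_by(.data$substance, .data$node) |>
    dplyr::summarise(
      value = mean(.data$value),
      n_entries = dplyr::n(),
      is_entry = any(.data$node == .data$food),
      .groups = "drop"
    ) |>
    dplyr::mutate(depth = food_depth(.data$node, delim))
  # an exact stored entry always wins over an aggregate at the same path
  entry_vals <- normalized |>
    dplyr::select("substance", node = "food", entry_value = "value")
  nodes <- nodes |>
    dplyr::left_join(entry_vals, by = c("substance", "node")) |>
    dplyr::mutate(value = ifelse(.data$is_entry, .data$entry_value,
                                 .data$value)) |>
    dplyr::select(-"entry_value")
  structure(list(nodes = nodes, delim = delim,
                 units = unique(normalized[c("substance", "unit")])),
            class = "concentration_index")
}

#' @export
print.concentration_index <- function(x, ...) {
  cat(sprintf("<concentration_index> %d substances, %d indexed nodes\n",
              length(unique(x$nodes$substance)), nrow(x$nodes)))
  invisible(x)
}

#' Look up a concentration with hierarchy fallback
#'
#' Walks the food's ancestor path from the most specific level to the
#' broadest and returns the first indexed value: an exact entry if present,
#' otherwise a parent-level aggregated mean. Foods with no indexed ancestor
#' contribute 0 and are tagged `unmatched`.
#'
#' @param index a [build_index()] object
#' @param food food path (vectorized)
#' @param substance single substance identifier
#' @param warn_unmatched warn once listing unmatched foods
#' @return tibble with columns `food`, `value`, `match_depth` (NA when
#'   unmatched), `provenance` (`exact`, `aggregate_depth<k>`, `unmatched`)
#' @export
lookup_concentration <- function(index, food, substance,
                                 warn_unmatched = TRUE) {
  stopifnot(inherits(index, "concentration_index"), length(substance) == 1L)
  nodes <- index$nodes[index$nodes$substance == substance, ]
  node_val <- stats::setNames(nodes$value, nodes$node)
  node_entry <- stats::setNames(nodes$is_entry, nodes$node)
  one <- function(f) {
    for (anc in food_ancestors(f, index$delim)) {
      if (!is.na(node_val[anc])) {
        d <- food_depth(anc, index$delim)
        prov <- if (isTRUE(node_entry[[anc]]) && anc == f) "exact"
                else sprintf("aggregate_depth%d", d)
        return(list(value = unname(node_val[[anc]]), depth = d, prov = prov))
      }
    }
    list(value = 0, depth = NA_integer_, prov = "unmatched")
  }
  hits <- lapply(food, one)
  out <- tibble::tibble(
    food = food,
    value = vapply(hits, `[[`, numeric(1), "value"),
    match_depth = vapply(hits, `[[`, integer(1), "depth"),
    provenance = vapply(hits, `[[`, character(1), "prov")
  )
  if (warn_unmatched && any(out$provenance == "unmatched")) {
    warning(sprintf("no %s concentration for food(s): %s (treated as 0)",
                    substance,
                    paste(unique(out$food[out$provenance == "unmatched"]),
                          collapse = ", ")),
            call. = FALSE)
  }
  out
}
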