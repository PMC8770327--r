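#' Substitution rules and scenarios
#'
#' A substitution rule redirects a fraction of the consumed mass of a set
#' of target foods (matched by ancestor-path prefix, so a rule written at
#' `"Grains>Pasta"` captures every pasta subtype) to a single replacement
#' food. A scenario is a named, ordered list of rules; each consumption
#' record is claimed by the first rule that matches it and is never
#' re-matched by a later rule.
#'
#' @param targets character vector of food path prefixes to substitute
#' @param replacement food path receiving the redirected mass
#' @param fraction fraction of each matching record's mass redirected,
#'   in \[0, 1\]
#' @return `substitution_rule()` returns a `substitution_rule` list.
#' @export
substitution_rule <- function(targets, replacement, fraction) {
  validate_food_paths(targets, what = "target path")
  validate_food_paths(replacement, what = "replacement path")
  stopifnot(length(replacement) == 1L, is.numeric(fraction),
            length(fraction) == 1L)
  if (fraction < 0 || fraction > 1) {
    stop("fraction must be in [0, 1]", call. = FALSE)
  }
  if (any(vapply(targets, function(t) food_matches_prefix(replacement, t),
                 logical(1)))) {
    stop("replacement food must not fall inside the target set", call. = FALSE)
  }
  structure(list(targets = targets, replacement = replacement,
                 fraction = fraction), class = "substitution_rule")
}

#' @rdname substitution_rule
#' @param name scenario name
#' @param rules list of [substitution_rule()] objects
#' @return `scenario()` returns a `scenario` list.
#' @export
scenario <- function(name, rules = list()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (inherits(rules, "substitution_rule")) rules <- list(rules)
  ok <- vapply(rules, inherits, logical(1), "substitution_rule")
  if (!all(ok)) stop("rules must be substitution_rule objects", call. = FALSE)
  structure(list(name = name, rules = rules), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> '%s' with %d rule(s)\n", x$name, length(x$rules)))
  for (r in x$rules) {
    cat(sprintf("  %.0f%% of {%s} -> %s\n", 100 * r$fraction,
                paste(r$targets, collapse = ", "), r$replacement))
  }
  invisible(x)
}

#' The reference (no-substitution) scenario
#'
#' An empty rule list: [apply_scenario()] is the identity.
#'
#' @return a `scenario` named `"reference"` with no rules
#' @export
reference_scenario <- function() scenario("reference", list())

#' Read a scenario from a YAML or JSON config
#'
#' Expected structure: `name`, and `rules` as a list of
#' `{targets: [paths], replacement: path, fraction: number}`.
#'
#' @param path config file (`.json` for JSON, otherwise YAML)
#' @return a [scenario()] object
#' @seealso [seaweed_scenario()] for the packaged 10% substitution config
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rules <- lapply(cfg$rules %||% list(), function(r) {
    substitution_rule(unlist(r$targets), r$replacement, r$fraction)
  })
  scenario(cfg$name %||% "scenario", rules)
}

#' Packaged 10% seaweed substitution scenario
#'
#' The case-study alternative scenario: 10% of the habitual consumption of
#' pasta, bacon and rocket lettuce per person per day is replaced by
#' seaweed pasta, seaweed bacon and seaweed lettuce respectively.
#'
#' @return a [scenario()] object
#' @export
seaweed_scenario <- function() {
  read_scenario(system.file("extdata", "seaweed_scenario.yaml",
                            package = "rbfood", mustWork = TRUE))
}

#' Apply a substitution scenario to a survey
#'
#' Each consumption record matched by a rule is split into a record of
#' `(1 - fraction)` times the original amount under the original food and
#' a record of `fraction` times the amount under the replacement food; the
#' split applies to cooked and raw amounts alike, so person-day mass is
#' conserved exactly on both bases. Records are claimed by the first
#' matching rule only, and replacement records are never re-substituted.
#'
#' @param survey a survey object
#' @param scn a [scenario()] object
#' @return a new survey with substituted records
#' @export
apply_scenario <- function(survey, scn) {
  stopifnot(inherits(survey, "survey"), inherits(scn, "scenario"))
  rec <- survey$records
  if (length(scn$rules) == 0L || nrow(rec) == 0L) return(survey)
  claimed <- rep(FALSE, nrow(rec))
  emptied <- rep(FALSE, nrow(rec))
  pieces <- list()
  for (r in scn$rules) {
    m <- !claimed & Reduce(`|`, lapply(r$targets, function(t) {
      food_matches_prefix(rec$food, t)
    }))
    claimed <- claimed | m
    if (!any(m) || r$fraction == 0) next
    moved <- rec[m, ]
    moved$food <- r$replacement
    moved$amount_cooked <- moved$amount_cooked * r$fraction
    moved$amount_raw <- moved$amount_raw * r$fraction
    rec$amount_cooked[m] <- rec$amount_cooked[m] * (1 - r$fraction)
    rec$amount_raw[m] <- rec$amount_raw[m] * (1 - r$fraction)
    if (r$fraction == 1) emptied <- emptied | m
    pieces[[length(pieces) + 1L]] <- moved
  }
  out <- dplyr::bind_rows(c(list(rec[!emptied, ]), pieces))
  new_survey(survey$individuals, out, n_days = survey$n_days)
}
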