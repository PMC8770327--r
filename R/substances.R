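#' Substances tracked by the assessment
#'
#' Registry of the nutrients and chemical contaminants handled by the
#' pipeline, with the unit conventions used throughout: nutrient intakes are
#' expressed per day (iodine in ug/day, sodium in mg/day) and are computed
#' from cooked amounts; contaminant exposures are expressed in ug/kg body
#' weight/day and are computed from raw amounts. Concentrations are carried
#' per kg food and the g/day -> kg/day and per-body-weight conversions each
#' happen exactly once, inside [compute_daily_intakes()].
#'
#' @return tibble with columns `substance`, `class` (nutrient/contaminant),
#'   `conc_unit`, `intake_unit`, `amount_basis` (cooked/raw).
#' @examples
#' substance_registry()
#' @export
substance_registry <- function() {
  tibble::tribble(
    ~substance,   ~class,        ~conc_unit, ~intake_unit,     ~amount_basis,
    "iodine",     "nutrient",    "ug/kg",    "ug/day",         "cooked",
    "sodium",     "nutrient",    "mg/kg",    "mg/day",         "cooked",
    "t_arsenic",  "contaminant", "ug/kg",    "ug/kg bw/day",   "raw",
    "i_arsenic",  "contaminant", "ug/kg",    "ug/kg bw/day",   "raw",
    "cadmium",    "contaminant", "ug/kg",    "ug/kg bw/day",   "raw",
    "lead",       "contaminant", "ug/kg",    "ug/kg bw/day",   "raw",
    "mercury",    "contaminant", "ug/kg",    "ug/kg bw/day",   "raw"
  )
}

substance_info <- function(substance) {
  reg <- substance_registry()
  hit <- reg[reg$substance == substance, ]
  if (nrow(hit) != 1L) {
    stop(sprintf("unknown substance '%s'; known: %s", substance,
                 paste(reg$substance, collapse = ", ")), call. = FALSE)
  }
  hit
}
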