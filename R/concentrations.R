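#' Read a substance concentration table
#'
#' One row per (food, substance) with the measured level per kg of food.
#' Required columns: `food` (hierarchy path), `substance` (see
#' [substance_registry()]), `value` (amount per kg), `unit`, `basis`
#' (`wet`/`dry`), `censoring` (`measured`, `LOD`, `LOQ`) and `censor_limit`
#' (the detection/quantification limit, required when censored). Censored
#' rows are later imputed at a configurable fraction of the limit
#' (default one half, see [resolve_censored()]); dry-weight rows are
#' divided by the dry-to-wet conversion factor at normalization.
#'
#' @param path delimited file with a one-line header (`.csv` comma, else tab)
#' @return tibble of validated concentration entries with `censoring`
#'   recoded to `measured` / `below_LOD` / `below_LOQ`
#' @seealso [seaweed_concentrations()], [normalize_concentrations()]
#' @export
read_concentrations <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0L) {
    warning("concentration file ", path, " is empty", call. = FALSE)
    return(tibble::tibble(food = character(), substance = character(),
                          value = double(), unit = character(),
                          basis = character(), censoring = character(),
                          censor_limit = double()))
  }
  need <- c("food", "substance", "value", "unit", "basis", "censoring")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("concentration file %s missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!"censor_limit" %in% names(df)) df$censor_limit <- NA_real_
  validate_concentrations(tibble::as_tibble(df))
}

recode_censoring <- function(x) {
  map <- c(measured = "measured", LOD = "below_LOD", LOQ = "below_LOQ",
           below_LOD = "below_LOD", below_LOQ = "below_LOQ")
  out <- unname(map[as.character(x)])
  if (anyNA(out)) {
    stop("unknown censoring token(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "),
         " (expected measured/LOD/LOQ)", call. = FALSE)
  }
  out
}

validate_concentrations <- function(df) {
  validate_food_paths(df$food)
  unknown <- setdiff(unique(df$substance), substance_registry()$substance)
  if (length(unknown)) {
    stop("unknown substance token(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  df$censoring <- recode_censoring(df$censoring)
  if (!all(df$basis %in% c("wet", "dry"))) {
    stop("basis must be 'wet' or 'dry'", call. = FALSE)
  }
  df$value <- as.double(df$value)
  df$censor_limit <- as.double(df$censor_limit)
  if (any(df$value < 0, na.rm = TRUE)) stop("negative concentration value",
                                            call. = FALSE)
  cens <- df$censoring != "measured"
  if (any(cens & (is.na(df$censor_limit) | df$censor_limit <= 0))) {
    stop("censored entries must carry censor_limit > 0", call. = FALSE)
  }
  df
}

#' Packaged concentration fixture for the seaweed substitution case study
#'
#' Concentrations of iodine (ug/kg), sodium (mg/kg) and heavy metals
#' (ug/kg) in regular pasta, bacon and rocket lettuce and in their
#' seaweed-derived analogues made from the kelp *Saccharina latissima*.
#' Regular-food levels are European monitoring means; seaweed heavy-metal
#' levels are kelp measurements on a dry-weight basis. Seaweed pasta and
#' seaweed lettuce are eaten rehydrated/fresh, so their heavy-metal entries
#' are stored dry-weight and converted to wet weight (factor 4.7) during
#' normalization; seaweed bacon is eaten as a dried product and keeps the
#' dry-matter levels as-is. Mercury in all three seaweed foods is below
#' the limit of quantification of 0.90 ug/kg.
#'
#' @return tibble of concentration entries (see [read_concentrations()])
#' @examples
#' seaweed_concentrations()
#' @export
seaweed_concentrations <- function() {
  read_concentrations(
    system.file("extdata", "seaweed_concentrations.tsv", package = "rbfood",
                mustWork = TRUE)
  )
}
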