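#' Hierarchical food codes
#'
#' Foods are identified by a classification path in the style of EFSA's
#' FoodEx2 hierarchy: an ordered sequence of labels from the broadest group
#' (level 1) down to the specific food, serialized as a single
#' delimiter-joined string, e.g. `"Grains>Pasta>Dried pasta"`. Broader
#' prefixes of a path are its ancestors; concentration lookups fall back to
#' the deepest ancestor that carries data.
#'
#' @param levels character vector of hierarchy labels, broadest first
#' @param delim delimiter used in the serialized path (default `">"`)
#' @return `food_code()` returns the serialized path string.
#' @examples
#' food_code(c("Grains", "Pasta"))
#' food_levels("Grains>Pasta>Dried pasta")
#' food_ancestors("Grains>Pasta>Dried pasta")
#' @export
food_code <- function(levels, delim = ">") {
  levels <- as.character(levels)
  if (length(levels) == 0L || any(!nzchar(trimws(levels)))) {
    stop("a food code needs at least one non-empty hierarchy label", call. = FALSE)
  }
  paste(trimws(levels), collapse = delim)
}

#' @rdname food_code
#' @param path serialized food path
#' @return `food_levels()` returns the character vector of labels.
#' @export
food_levels <- function(path, delim = ">") {
  strsplit(path, delim, fixed = TRUE)[[1L]]
}

#' @rdname food_code
#' @return `food_depth()` returns the number of hierarchy levels.
#' @export
food_depth <- function(path, delim = ">") {
  lengths(strsplit(path, delim, fixed = TRUE))
}

#' @rdname food_code
#' @param include_self include the full path itself as the deepest entry
#' @return `food_ancestors()` returns paths from deepest to broadest.
#' @export
food_ancestors <- function(path, delim = ">", include_self = TRUE) {
  lv <- food_levels(path, delim)
  d <- length(lv)
  depths <- if (include_self) rev(seq_len(d)) else rev(seq_len(d - 1L))
  vapply(depths, function(k) paste(lv[seq_len(k)], collapse = delim), character(1))
}

# TRUE where `path` equals `prefix` or descends from it
food_matches_prefix <- function(path, prefix, delim = ">") {
  path == prefix | startsWith(path, paste0(prefix, delim))
}

validate_food_paths <- function(paths, delim = ">", what = "food code") {
  bad <- !nzchar(trimws(paths)) |
    vapply(strsplit(paths, delim, fixed = TRUE),
           function(lv) length(lv) == 0L || any(!nzchar(trimws(lv))), logical(1))
  if (any(bad)) {
    stop(sprintf("invalid %s(s): %s", what,
                 paste(unique(paths[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(paths)
}
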