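#' The twelve taxonomic animal classes
#'
#' Animal classes are a subset of the clusters used in semantic-fluency
#' cluster schemes: every class is a cluster, but clusters such as "pets" or
#' "zoo animals" are not taxonomic classes and are never eligible for series
#' detection.
#'
#' @return Character vector of the twelve taxonomic class labels.
#' @export
#' @examples
#' taxonomic_classes()
taxonomic_classes <- function() {
  c("Bird", "Bovine", "Canine", "Deers", "Feline", "Fish", "Insects",
    "Primates", "Reptile/Amphibian", "Rodents", "Weasels", "Worms")
}

#' Normalize a fluency item string
#'
#' Lowercases, trims, and collapses internal whitespace. No stemming: plural
#' handling is a transcript-scoring concern, not a lookup concern.
#'
#' @param x Character vector of raw item strings.
#' @return Character vector of normalized items.
#' @export
normalize_item <- function(x) {
  stringr::str_squish(stringr::str_to_lower(x))
}

new_class_scheme <- function(entries, classes, language = NA_character_) {
  structure(
    list(entries = entries, classes = classes, language = language,
         lookup = split(entries$class, entries$item)),
    class = "class_scheme"
  )
}

#' Build a class scheme from an item/class table
#'
#' @param entries Data frame with columns `item` and `class`, one row per
#'   item-class membership. Items are normalized; duplicate rows are kept in
#'   the table (flagged by [validate_scheme()]) but collapse in lookups.
#' @param taxonomic Character vector of class labels to mark as taxonomic
#'   animal classes; defaults to the canonical twelve. Classes referenced by
#'   entries but not listed here are retained as mere clusters.
#' @param language Optional free-text language tag.
#' @return A `class_scheme` object.
#' @export
class_scheme <- function(entries, taxonomic = taxonomic_classes(),
                         language = NA_character_) {
  stopifnot(is.data.frame(entries), all(c("item", "class") %in% names(entries)))
  entries <- tibble::tibble(
    item = normalize_item(as.character(entries$item)),
    class = stringr::str_squish(as.character(entries$class))
  )
  if (any(entries$item == "" | is.na(entries$item))) {
    stop("scheme contains empty item strings after normalization", call. = FALSE)
  }
  if (any(entries$class == "" | is.na(entries$class))) {
    stop("scheme contains empty class labels", call. = FALSE)
  }
  all_classes <- sort(unique(c(entries$class, taxonomic)))
  classes <- tibble::tibble(
    class = all_classes,
    is_taxonomic_class = all_classes %in% taxonomic
  )
  new_class_scheme(entries, classes, language)
}

#' Load an animal class scheme from a delimited file
#'
#' Reads a two-column delimited text file (`item,class`), one row per
#' membership, comma- or tab-separated; lines starting with `#` are comments.
#' Items occurring in several rows accumulate multiple classes (e.g. "seal"
#' as both Fish-adjacent and Weasels in some schemes).
#'
#' @param path Path to the scheme file.
#' @param taxonomic Class labels to mark as taxonomic; defaults to the
#'   canonical twelve. Unlisted classes (e.g. "pets") stay non-taxonomic.
#' @param language Optional language tag stored on the scheme.
#' @return A `class_scheme` object.
#' @export
#' @examples
#' path <- system.file("extdata", "demo_scheme.csv", package = "animalfluency")
#' scheme <- load_scheme(path)
#' classes_of(scheme, "robin")
load_scheme <- function(path, taxonomic = taxonomic_classes(),
                        language = NA_character_) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("scheme file is empty: ", path, call. = FALSE)
  rows <- lines[keep]
  line_no <- which(keep)
  delim <- if (any(grepl("\t", rows))) "\t" else ","
  parts <- strsplit(rows, delim, fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("malformed scheme row at line ", line_no[bad[1L]],
         ": expected 2 fields, got ", lengths(parts)[bad[1L]], call. = FALSE)
  }
  mat <- do.call(rbind, parts)
  entries <- tibble::tibble(item = mat[, 1L], class = mat[, 2L])
  # drop a header row if present
  if (nrow(entries) > 0L &&
      identical(normalize_item(entries$item[1L]), "item") &&
      identical(tolower(entries$class[1L]), "class")) {
    entries <- entries[-1L, , drop = FALSE]
    if (nrow(entries) == 0L) stop("scheme file is empty: ", path, call. = FALSE)
  }
  class_scheme(entries, taxonomic = taxonomic, language = language)
}

#' Write a class scheme back to a delimited file
#'
#' Inverse of [load_scheme()]: writes one `item,class` row per membership so
#' that a load/write/load round trip reproduces the entries table.
#'
#' @param scheme A `class_scheme`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "class_scheme"))
  readr::write_csv(scheme$entries, path, col_names = FALSE)
  invisible(path)
}

#' Look up the classes of an item
#'
#' Pure, normalized lookup: `classes_of(scheme, "ROBIN ")` equals
#' `classes_of(scheme, "robin")`. Unknown items yield an empty character
#' vector.
#'
#' @param scheme A `class_scheme`.
#' @param item A single item string (raw; normalized internally).
#' @return Character vector of class labels (possibly empty).
#' @export
classes_of <- function(scheme, item) {
  stopifnot(inherits(scheme, "class_scheme"), length(item) == 1L)
  hit <- scheme$lookup[[normalize_item(item)]]
  if (is.null(hit)) character(0) else unique(hit)
}

#' Validate a class scheme
#'
#' Reports (as warnings, not errors) duplicate item-class rows, registered
#' classes with no items, and items assigned to more than two classes.
#'
#' @param scheme A `class_scheme`.
#' @return A tibble with columns `type`, `what`, `message`; zero rows for a
#'   clean scheme.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  ent <- scheme$entries
  dup <- ent |>
    dplyr::count(.data$item, .data$class, name = "n_rows") |>
    dplyr::filter(.data$n_rows > 1L)
  empty <- scheme$classes |>
    dplyr::filter(!.data$class %in% ent$class)
  many <- ent |>
    dplyr::distinct(.data$item, .data$class) |>
    dplyr::count(.data$item, name = "n_classes") |>
    dplyr::filter(.data$n_classes > 2L)
  dplyr::bind_rows(
    tibble::tibble(
      type = rep("duplicate_row", nrow(dup)),
      what = paste(dup$item, dup$class, sep = "/"),
      message = sprintf("item '%s' listed %d times under class '%s'",
                        dup$item, dup$n_rows, dup$class)
    ),
    tibble::tibble(
      type = rep("empty_class", nrow(empty)),
      what = empty$class,
      message = sprintf("class '%s' has no items", empty$class)
    ),
    tibble::tibble(
      type = rep("many_classes", nrow(many)),
      what = many$item,
      message = sprintf("item '%s' belongs to %d classes", many$item,
                        many$n_classes)
    )
  )
}

#' @export
print.class_scheme <- function(x, ...) {
  n_tax <- sum(x$classes$is_taxonomic_class)
  cat("<class_scheme> ", dplyr::n_distinct(x$entries$item), " items, ",
      nrow(x$classes), " classes (", n_tax, " taxonomic)",
      if (!is.na(x$language)) paste0(", language: ", x$language), "\n",
      sep = "")
  invisible(x)
}

taxonomic_labels <- function(scheme) {
  scheme$classes$class[scheme$classes$is_taxonomic_class]
}
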