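#' Construct a food-knowledge instrument
#'
#' An instrument is an ordered set of food items, each assigned to a food
#' category (e.g. banana, dairy) and a Nova classification group, together
#' with the bounds of the healthiness rating scale. Scoring compares ratings
#' within each category, so every category must contain exactly one item from
#' each of the three scored Nova groups: G1 (unprocessed/minimally processed),
#' G3 (processed) and G4 (ultra-processed). Processed culinary ingredients
#' (G2) are not rated in isolation and never appear in an instrument.
#'
#' @param items A data frame with columns `item_id`, `label`, `category`,
#'   `nova_group`. `item_id` must be unique; `nova_group` must be one of
#'   `"G1"`, `"G3"`, `"G4"`.
#' @param scale Length-2 integer vector, the inclusive rating bounds
#'   (default 1-10).
#' @param name Display name of the instrument.
#'
#' @return An object of class `nova_instrument`: a list with elements
#'   `name`, `scale` (list with `min`, `max`) and `items` (a tibble).
#' @seealso [default_instrument()], [read_instrument()]
#' @examples
#' toy <- nova_instrument(
#'   items = data.frame(
#'     item_id = c("apple", "applesauce", "apple_soda"),
#'     label = c("Fresh apple", "Canned applesauce", "Apple-flavored soda"),
#'     category = "apple",
#'     nova_group = c("G1", "G3", "G4")
#'   ),
#'   name = "toy"
#' )
#' toy
#' @export
nova_instrument <- function(items, scale = c(1L, 10L), name = "custom") {
  items <- check_data_frame(items, "items")
  check_cols(items, c("item_id", "label", "category", "nova_group"), "items")
  items <- dplyr::mutate(
    items,
    dplyr::across(c("item_id", "label", "category", "nova_group"), as.character)
  )
  if (length(scale) != 2 || !all(is_wholenumber(scale)) || scale[1] >= scale[2]) {
    nv_abort("`scale` must be two integers with min < max.")
  }
  x <- structure(
    list(
      name = as.character(name)[1],
      scale = list(min = as.integer(scale[1]), max = as.integer(scale[2])),
      items = tibble::as_tibble(items[, c("item_id", "label", "category", "nova_group")])
    ),
    class = "nova_instrument"
  )
  validate_instrument(x)
}

validate_instrument <- function(x) {
  items <- x$items
  bad_grp <- setdiff(unique(items$nova_group), c("G1", "G3", "G4"))
  if (length(bad_grp) > 0) {
    nv_abort(sprintf(
      "Unknown Nova group code(s): %s. Instruments use only G1, G3, G4.",
      paste(bad_grp, collapse = ", ")
    ))
  }
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup) > 0) {
    nv_abort(sprintf("Duplicate item_id(s): %s.", paste(unique(dup), collapse = ", ")))
  }
  # every category must be a complete triad: exactly one item per group
  for (cat in unique(items$category)) {
    grp <- items$nova_group[items$category == cat]
    missing <- setdiff(c("G1", "G3", "G4"), grp)
    extra <- grp[duplicated(grp)]
    if (length(missing) > 0) {
      nv_abort(sprintf(
        "Category '%s' is missing item(s) for group(s): %s.",
        cat, paste(missing, collapse = ", ")
      ))
    }
    if (length(extra) > 0) {
      nv_abort(sprintf(
        "Category '%s' has more than one item for group(s): %s.",
        cat, paste(unique(extra), collapse = ", ")
      ))
    }
  }
  x
}

#' Instrument category names
#'
#' @param instrument A [nova_instrument()].
#' @return Character vector of category names, in order of first appearance.
#' @export
instrument_categories <- function(instrument) {
  stopifnot(inherits(instrument, "nova_instrument"))
  unique(instrument$items$category)
}

#' The bundled Nova-Conhecimento instrument
#'
#' Returns the Brazilian 12-item food-processing knowledge instrument: four
#' food categories (banana, beef, corn, dairy), each represented by one
#' unprocessed/minimally processed (G1), one processed (G3) and one
#' ultra-processed (G4) item, rated for healthiness on a 1-10 scale.
#'
#' @return A `nova_instrument` with 12 items in 4 categories.
#' @examples
#' default_instrument()
#' @export
default_instrument <- function() {
  items <- tibble::tribble(
    ~item_id,              ~label,                               ~category, ~nova_group,
    "banana_fresh",        "Fresh banana",                       "banana",  "G1",
    "banana_sweet",        "Banana sweet with added sugar",      "banana",  "G3",
    "banana_cereal_bar",   "Banana-flavored cereal bar",         "banana",  "G4",
    "beef_fresh",          "Fresh beef",                         "beef",    "G1",
    "beef_dried",          "Dried beef with added salt",         "beef",    "G3",
    "beef_meatballs",      "Frozen beef meatballs",              "beef",    "G4",
    "corn_cob",            "Fresh corn on the cob",              "corn",    "G1",
    "corn_canned",         "Canned corn",                        "corn",    "G3",
    "corn_bread",          "Corn-flavored sliced bread",         "corn",    "G4",
    "milk_whole",          "Pasteurized whole cow's milk",       "dairy",   "G1",
    "minas_cheese",        "Minas cheese",                       "dairy",   "G3",
    "dairy_beverage",      "Strawberry-flavored dairy beverage", "dairy",   "G4"
  )
  nova_instrument(items, scale = c(1L, 10L), name = "Nova-Conhecimento")
}

#' Read or write an instrument definition (JSON)
#'
#' The canonical on-disk form is a JSON document
#' `{name, scale: {min, max}, items: [{item_id, label, category, nova_group}]}`.
#' Validation (complete category triads, unique ids, known group codes) runs
#' at load time, so a successfully read instrument is always scoreable.
#'
#' @param path Path to a JSON file.
#' @return `read_instrument()` returns a `nova_instrument`;
#'   `write_instrument()` returns `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".json")
#' write_instrument(default_instrument(), path)
#' identical(read_instrument(path), default_instrument())
#' @export
read_instrument <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      nv_abort(
        sprintf("Could not parse instrument JSON '%s': %s", path, conditionMessage(e)),
        class = "novascore_parse_error"
      )
    }
  )
  for (field in c("name", "scale", "items")) {
    if (is.null(doc[[field]])) {
      nv_abort(sprintf("Instrument document is missing field '%s'.", field),
        class = "novascore_parse_error"
      )
    }
  }
  if (is.null(doc$scale$min) || is.null(doc$scale$max)) {
    nv_abort("Instrument 'scale' must provide 'min' and 'max'.",
      class = "novascore_parse_error"
    )
  }
  items <- tibble::as_tibble(doc$items)
  check_cols(items, c("item_id", "label", "category", "nova_group"), "items")
  nova_instrument(items,
    scale = c(doc$scale$min, doc$scale$max),
    name = doc$name
  )
}

#' @rdname read_instrument
#' @param instrument A `nova_instrument` to serialize.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "nova_instrument"))
  doc <- list(
    name = instrument$name,
    scale = instrument$scale,
    items = instrument$items
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.nova_instrument <- function(x, ...) {
  cat(sprintf(
    "<nova_instrument> %s: %d items, %d categories, scale %d-%d\n",
    x$name, nrow(x$items), length(instrument_categories(x)),
    x$scale$min, x$scale$max
  ))
  print(x$items, n = nrow(x$items))
  invisible(x)
}
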