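# Packaged reference tables: the published IVI ranking, the plant species x
# item x core/periphery table, and the network-attribute summary. "-" (or an
# empty field) denotes absence of a species from a habitat.

#' Load a packaged reference table
#'
#' Three tables from the source study are shipped with the package:
#' \describe{
#'   \item{`table2_ivi`}{the ten tree species with the highest importance value
#'     index (IVI) per habitat.}
#'   \item{`table3_items`}{all 37 consumed plant species with the item codes
#'     consumed per habitat and the percentage of core-periphery runs in which
#'     each species was classified core or periphery.}
#'   \item{`table4_attributes`}{network-level attributes (node counts, NODF,
#'     links per species, connectance, interaction diversity, H2') per habitat.}
#' }
#'
#' @param name One of `"table2_ivi"`, `"table3_items"`, `"table4_attributes"`.
#' @return A data.frame with the published values.
#' @export
load_fixture <- function(name = c("table2_ivi", "table3_items", "table4_attributes")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "howlernet")
  if (path == "") stop("fixture not found: ", name, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  encoding = "UTF-8")
}

is_absent <- function(x) {
  x <- trimws(x)
  is.na(x) | x == "" | x == "-" | x == "–"
}

parse_items <- function(x) {
  if (is_absent(x)) character(0) else strsplit(trimws(x), "\\s+")[[1]]
}

#' Species bookkeeping from the item table
#'
#' Counts plant species per habitat from the packaged species x item table: a
#' species counts toward a habitat iff it has at least one item code recorded
#' there. Returns per-habitat counts, the total number of distinct species,
#' the number shared between habitats, and the distinct item codes in use.
#'
#' @param table3 The `table3_items` fixture (default: loaded from the package).
#' @return A list with elements `continuous`, `fragment`, `total`, `shared`,
#'   `items` (sorted character vector of item codes), and the per-habitat
#'   species name vectors `continuous_species`, `fragment_species`.
#' @export
count_species_by_habitat <- function(table3 = load_fixture("table3_items")) {
  cont <- !is_absent(table3$continuous_items)
  frag <- !is_absent(table3$fragment_items)
  items <- sort(unique(unlist(lapply(
    c(table3$continuous_items, table3$fragment_items), parse_items
  ))))
  list(
    continuous = sum(cont),
    fragment = sum(frag),
    total = nrow(table3),
    shared = sum(cont & frag),
    items = items,
    continuous_species = table3$species[cont],
    fragment_species = table3$species[frag]
  )
}

# Item sets per species for one habitat, as a named list (used by the
# synthetic-data preset). Absent species are dropped.
fixture_item_sets <- function(habitat, table3 = load_fixture("table3_items")) {
  habitat <- match.arg(habitat, habitats())
  col <- if (habitat == "continuous") "continuous_items" else "fragment_items"
  present <- !is_absent(table3[[col]])
  sets <- lapply(table3[[col]][present], parse_items)
  names(sets) <- table3$species[present]
  sets
}
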