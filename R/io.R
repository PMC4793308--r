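# Reading, validating and writing the tabular formats: focal feeding
# observations, vegetation transects, and interaction matrices. All files are
# comma-separated UTF-8 with a header row.

obs_columns <- c("record_id", "habitat", "site_id", "individual_id", "sex",
                 "age_class", "plant_species", "item", "duration")

transect_columns <- c("site_id", "habitat", "transect_id", "x", "y",
                      "species", "dbh")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

validate_observations <- function(df) {
  check_columns(df, obs_columns, "observations")
  if (nrow(df) == 0) return(df)
  df$plant_species <- trimws(df$plant_species)
  df$item <- trimws(df$item)
  bad <- which(!df$item %in% plant_items())
  if (length(bad) > 0) {
    stop(sprintf("unknown item code '%s' at row %d (valid: %s)",
                 df$item[bad[1]], bad[1], paste(plant_items(), collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!df$habitat %in% habitats())
  if (length(bad) > 0) {
    stop(sprintf("unknown habitat '%s' at row %d", df$habitat[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(!df$sex %in% c("F", "M"))
  if (length(bad) > 0) {
    stop(sprintf("unknown sex '%s' at row %d", df$sex[bad[1]], bad[1]),
         call. = FALSE)
  }
  bad <- which(!df$age_class %in% c("adult", "juvenile", "infant"))
  if (length(bad) > 0) {
    stop(sprintf("unknown age class '%s' at row %d", df$age_class[bad[1]], bad[1]),
         call. = FALSE)
  }
  df$duration <- as.numeric(df$duration)
  bad <- which(!is.finite(df$duration) | df$duration < 0)
  if (length(bad) > 0) {
    stop(sprintf("invalid duration at row %d (must be finite and >= 0)", bad[1]),
         call. = FALSE)
  }
  df
}

#' Read focal feeding observations
#'
#' Reads a CSV of focal-animal feeding records (one row per feeding bout) and
#' validates it: the seven plant-item codes, habitat/sex/age-class levels, and
#' non-negative finite durations (minutes). Plant species names are trimmed of
#' surrounding whitespace and otherwise matched as opaque strings.
#'
#' @param path Path to a CSV with columns `record_id`, `habitat`, `site_id`,
#'   `individual_id`, `sex`, `age_class`, `plant_species`, `item`, `duration`.
#' @return A data.frame of validated records (possibly with zero rows).
#' @seealso [build_interaction_matrix()], [write_observations()]
#' @export
read_observations <- function(path) {
  # all-character read: bare "F"/"T" in sex or species must not become logical
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  check_columns(df, obs_columns, "observations")
  df$record_id <- utils::type.convert(df$record_id, as.is = TRUE)
  df$duration <- as.numeric(df$duration)
  validate_observations(df)
}

#' Write focal feeding observations
#'
#' @param records Data.frame of observation records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  check_columns(records, obs_columns, "observations")
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

validate_transects <- function(df) {
  check_columns(df, transect_columns, "transects")
  if (nrow(df) == 0) return(df)
  df$species <- trimws(df$species)
  df$dbh <- as.numeric(df$dbh)
  bad <- which(!is.finite(df$dbh) | df$dbh < 10)
  if (length(bad) > 0) {
    stop(sprintf("invalid dbh at row %d (sampling rule: dbh >= 10 cm)", bad[1]),
         call. = FALSE)
  }
  bad <- which(!df$habitat %in% habitats())
  if (length(bad) > 0) {
    stop(sprintf("unknown habitat '%s' at row %d", df$habitat[bad[1]], bad[1]),
         call. = FALSE)
  }
  df
}

#' Read vegetation transect records
#'
#' One row per stem (dbh >= 10 cm) recorded in a 50 x 2 m transect.
#'
#' @param path Path to a CSV with columns `site_id`, `habitat`, `transect_id`,
#'   `x`, `y`, `species`, `dbh`.
#' @return Validated data.frame of transect records.
#' @export
read_transects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = "character")
  check_columns(df, transect_columns, "transects")
  for (col in c("x", "y", "dbh")) df[[col]] <- as.numeric(df[[col]])
  df$transect_id <- utils::type.convert(df$transect_id, as.is = TRUE)
  validate_transects(df)
}

#' Write vegetation transect records
#'
#' @param transects Data.frame of transect records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transects <- function(transects, path) {
  check_columns(transects, transect_columns, "transects")
  utils::write.csv(transects, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build an individual x plant interaction matrix
#'
#' Aggregates feeding records from one habitat into an interaction matrix with
#' one row per monkey and one column per plant species. Cells hold the number
#' of feeding records (`count`), the summed feeding duration in minutes
#' (`minutes`), or presence/absence (`binary`).
#'
#' If `individuals` is supplied (a data.frame with at least `individual_id` and
#' `habitat`), every censused individual of the habitat gets a row even when it
#' was never seen feeding; all-zero rows are retained with a warning so node
#' counts match the census (degree-0 nodes contribute 0 to nestedness pairs).
#'
#' @param records Data.frame of observation records (see [read_observations()]).
#' @param habitat `"continuous"` or `"fragment"`.
#' @param weighting One of `"count"`, `"minutes"`, `"binary"`.
#' @param individuals Optional census data.frame; default uses the individuals
#'   present in `records`.
#' @return Numeric matrix, rows = individuals, columns = plant species.
#' @examples
#' recs <- data.frame(
#'   record_id = 1:3, habitat = "continuous", site_id = "s1",
#'   individual_id = c("m1", "m1", "m2"), sex = "F", age_class = "adult",
#'   plant_species = c("A", "A", "B"), item = "MF", duration = 5
#' )
#' build_interaction_matrix(recs, "continuous")
#' @export
build_interaction_matrix <- function(records, habitat,
                                     weighting = c("count", "minutes", "binary"),
                                     individuals = NULL) {
  weighting <- match.arg(weighting)
  habitat <- match.arg(habitat, habitats())
  records <- validate_observations(records)
  rec <- records[records$habitat == habitat, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop(sprintf("no observation records for habitat '%s'", habitat), call. = FALSE)
  }
  ids <- sort(unique(rec$individual_id))
  if (!is.null(individuals)) {
    census <- individuals[individuals$habitat == habitat, , drop = FALSE]
    ids <- sort(unique(c(ids, census$individual_id)))
  }
  sps <- sort(unique(rec$plant_species))
  web <- matrix(0, nrow = length(ids), ncol = length(sps),
                dimnames = list(ids, sps))
  val <- if (weighting == "minutes") rec$duration else rep(1, nrow(rec))
  agg <- tapply(val, list(rec$individual_id, rec$plant_species), sum)
  web[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  if (weighting == "binary") web <- as_binary(web)
  zero <- rowSums(web) == 0
  if (any(zero)) {
    warning(sprintf("retaining %d individual(s) with no feeding records as all-zero rows: %s",
                    sum(zero), paste(ids[zero], collapse = ", ")), call. = FALSE)
  }
  web
}

#' Read / write an interaction matrix as CSV
#'
#' Matrices are stored with row labels (individuals) in the first column and
#' plant species as the remaining column headers.
#'
#' @param path CSV path.
#' @return `read_matrix_csv`: a numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        encoding = "UTF-8")
  web <- as.matrix(df[, -1, drop = FALSE])
  mode(web) <- "numeric"
  rownames(web) <- df[[1]]
  check_web(web)
  web
}

#' @rdname read_matrix_csv
#' @param web Numeric interaction matrix.
#' @export
write_matrix_csv <- function(web, path) {
  check_web(web)
  df <- data.frame(individual = rownames(web), web, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
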