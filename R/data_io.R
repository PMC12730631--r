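#' @importFrom utils read.table write.table head
NULL

# closed vocabularies for the trait table
TAXON_CLASSES <- c("rotifer", "copepod_cladoceran", "protozoan", "larva", "other")
FEEDING_HABITS <- c("filter", "carnivore", "algivore", "bacterivore",
                    "detritivore", "fungivore", "saprotroph", "raptor",
                    "omnivore", "photosynthetic")

COMMUNITY_COLS <- c("sample_id", "stratum", "season", "species_id", "n", "v")
TRAIT_COLS <- c("species_id", "taxon_class", "body_size_mm", "feeding_habit")

#' Construct a validated community dataset
#'
#' A community dataset is the long-form record of a plankton survey: one row
#' per (sample, species) pair actually counted, plus sampling metadata.
#' Species absent from a sample are implicit zeros; every matrix view of the
#' data closes over the full species x sample universe.
#'
#' @param records data.frame with columns `sample_id`, `stratum`, `season`,
#'   `species_id`, `n` (individuals counted, integer >= 0), `v` (filtered
#'   volume in m^3, > 0) and optionally `biomass` (wet weight, mg m^-3).
#' @return An object of class `community_dataset`: the validated records
#'   plus a `samples` table (one row per sample with its stratum and season)
#'   and the ordered `species` index.
#' @export
community_dataset <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(COMMUNITY_COLS, names(records))
  if (length(missing_cols) > 0)
    stop("community table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0)
    stop("no records: community table has a header but no data rows")

  records$sample_id <- as.character(records$sample_id)
  records$stratum <- as.character(records$stratum)
  records$season <- as.character(records$season)
  records$species_id <- as.character(records$species_id)

  for (col in c("n", "v")) {
    if (!is.numeric(records[[col]]))
      stop("column '", col, "' must be numeric")
  }
  bad_n <- which(records$n < 0 | records$n != floor(records$n))
  if (length(bad_n) > 0)
    stop("column 'n' must hold integer counts >= 0; first bad row: ", bad_n[1])
  bad_v <- which(!(records$v > 0))
  if (length(bad_v) > 0)
    stop("column 'v' (filtered volume) must be > 0; first bad row: ", bad_v[1])
  if ("biomass" %in% names(records)) {
    if (!is.numeric(records$biomass) || any(records$biomass < 0, na.rm = TRUE))
      stop("column 'biomass' must be numeric >= 0")
  }

  key <- paste(records$sample_id, records$species_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (sample_id, species_id) pair: (",
         records$sample_id[dup[1]], ", ", records$species_id[dup[1]], ")")

  # a sample must carry a single (stratum, season) annotation
  meta <- unique(records[, c("sample_id", "stratum", "season")])
  if (anyDuplicated(meta$sample_id))
    stop("sample_id annotated with more than one stratum/season: ",
         meta$sample_id[duplicated(meta$sample_id)][1])
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  structure(
    list(records = records,
         samples = meta,
         species = sort(unique(records$species_id))),
    class = "community_dataset")
}

#' @export
print.community_dataset <- function(x, ...) {
  cat("<community_dataset> ", length(x$species), " species x ",
      nrow(x$samples), " samples (", nrow(x$records), " records)\n", sep = "")
  cat("  strata:  ", paste(unique(x$samples$stratum), collapse = ", "), "\n")
  cat("  seasons: ", paste(unique(x$samples$season), collapse = ", "), "\n")
  invisible(x)
}

# sniff the delimiter from the header line: tab wins if present, else comma
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0) stop("empty file: ", path)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a long-format community table
#'
#' Expects delimited UTF-8 text (comma or tab, auto-detected) with a header
#' row naming at least `sample_id, stratum, season, species_id, n, v`, and
#' optionally `biomass`. One row per (sample, species) pair observed.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) auto-detects.
#' @return A [community_dataset()].
#' @export
read_community_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- delim %||% detect_delim(path)
  df <- read.table(path, header = TRUE, sep = delim, quote = "\"",
                   stringsAsFactors = FALSE, comment.char = "",
                   fileEncoding = "UTF-8")
  community_dataset(df)
}

#' Read a species trait table
#'
#' The trait table drives functional-group assignment. Columns:
#' `species_id`, `taxon_class` (one of rotifer, copepod_cladoceran,
#' protozoan, larva, other), `body_size_mm` (required for
#' copepod_cladoceran, may be empty otherwise), `feeding_habit` (closed
#' vocabulary, see Details) and optional free-text `notes` (the token
#' `nauplius` flags copepod nauplii).
#'
#' @details Recognised feeding habits: `r paste(FEEDING_HABITS, collapse = ", ")`.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` auto-detects.
#' @return A `trait_table` data.frame keyed by `species_id`.
#' @export
read_trait_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  delim <- delim %||% detect_delim(path)
  df <- read.table(path, header = TRUE, sep = delim, quote = "\"",
                   stringsAsFactors = FALSE, comment.char = "",
                   fileEncoding = "UTF-8", na.strings = c("NA", ""))
  trait_table(df)
}

#' Construct a validated trait table
#'
#' @param df data.frame with the columns described in [read_trait_table()].
#' @return The validated data.frame with class `trait_table`.
#' @export
trait_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(setdiff(TRAIT_COLS, "body_size_mm"), names(df))
  if (length(missing_cols) > 0)
    stop("trait table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"body_size_mm" %in% names(df)) df$body_size_mm <- NA_real_
  if (!"notes" %in% names(df)) df$notes <- ""
  df$species_id <- as.character(df$species_id)
  df$taxon_class <- as.character(df$taxon_class)
  df$feeding_habit <- as.character(df$feeding_habit)
  df$body_size_mm <- as.numeric(df$body_size_mm)
  df$notes <- ifelse(is.na(df$notes), "", as.character(df$notes))

  if (anyDuplicated(df$species_id))
    stop("duplicate species_id in trait table: ",
         df$species_id[duplicated(df$species_id)][1])
  bad_class <- setdiff(unique(df$taxon_class), TAXON_CLASSES)
  if (length(bad_class) > 0)
    stop("unknown taxon_class: ", paste(bad_class, collapse = ", "))
  bad_habit <- setdiff(unique(df$feeding_habit), c(FEEDING_HABITS, NA))
  if (length(bad_habit) > 0)
    stop("unknown feeding_habit: ", paste(bad_habit, collapse = ", "))
  need_size <- df$taxon_class == "copepod_cladoceran"
  if (any(need_size & (is.na(df$body_size_mm) | df$body_size_mm <= 0)))
    stop("copepod_cladoceran species must carry body_size_mm > 0: ",
         paste(df$species_id[need_size &
             (is.na(df$body_size_mm) | df$body_size_mm <= 0)], collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Species x sample abundance (or biomass) matrix
#'
#' Converts the long records to a dense species x sample matrix. Abundance
#' is individuals per cubic metre, `N = n / v`: the count divided by the
#' volume of water filtered. Pairs absent from the records are exact zeros,
#' closing the universe required by presence/absence statistics.
#'
#' @param ds a [community_dataset()].
#' @param measure `"abundance"` (ind m^-3, default), `"biomass"`
#'   (mg m^-3; requires the biomass column), or `"counts"` (raw individuals).
#' @return Numeric matrix, rows = species (sorted), cols = samples (sorted).
#' @export
abundance_matrix <- function(ds, measure = c("abundance", "biomass", "counts")) {
  stopifnot(inherits(ds, "community_dataset"))
  measure <- match.arg(measure)
  rec <- ds$records
  if (measure == "biomass" && !"biomass" %in% names(rec))
    stop("dataset has no biomass column")
  val <- switch(measure,
                abundance = rec$n / rec$v,
                biomass = rec$biomass,
                counts = rec$n)
  m <- matrix(0, nrow = length(ds$species), ncol = nrow(ds$samples),
              dimnames = list(ds$species, ds$samples$sample_id))
  m[cbind(match(rec$species_id, ds$species),
          match(rec$sample_id, ds$samples$sample_id))] <- val
  m
}

#' Write a result table or matrix to disk
#'
#' All downstream result objects (data.frames and labelled matrices) share
#' one writer so the on-disk dialect is uniform: UTF-8, tab-delimited with
#' header (or JSON), floats at 6 significant digits by default so a
#' write-read round trip preserves values at stored precision.
#'
#' @param x data.frame or matrix.
#' @param path output file path.
#' @param format `"delimited"` (TSV, default) or `"json"`.
#' @param digits significant digits for floating-point columns.
#' @export
write_results <- function(x, path, format = c("delimited", "json"),
                          digits = 6) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", matrix = "rowmajor", na = "null")
    return(invisible(path))
  }
  if (is.matrix(x)) {
    df <- as.data.frame(x)
    df <- cbind(id = rownames(x) %||% seq_len(nrow(x)), df)
  } else {
    df <- as.data.frame(x)
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(col) signif(col, digits))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a table written by [write_results()]
#'
#' @param path file path to a delimited result table.
#' @return data.frame.
#' @export
read_results <- function(path) {
  read.table(path, header = TRUE, sep = "\t", quote = "\"",
             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
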