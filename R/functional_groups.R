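# The 17-group trait-based classification for freshwater/estuarine
# zooplankton: rotifers by feeding habit, copepods/cladocerans by body-size
# class x feeding habit, protozoans by trophic mode. Larvae are excluded
# from group-level analysis except copepod nauplii, which the field's usage
# folds into SCF.

GROUP_CODES <- c("RF", "RC", "RP",
                 "SCF", "SCC", "MCF", "MCC", "LCF", "LCC",
                 "PP", "PA", "PB", "PD", "PF", "PS", "PR", "PN",
                 "EXCLUDED")

ROTIFER_MAP <- c(filter = "RF", carnivore = "RC", algivore = "RP")
PROTOZOAN_MAP <- c(photosynthetic = "PP", algivore = "PA", bacterivore = "PB",
                   detritivore = "PD", fungivore = "PF", saprotroph = "PS",
                   raptor = "PR", omnivore = "PN")
COPEPOD_MAP <- c(filter = "CF", carnivore = "CC")

# size classes: < 0.7 small, 0.7-1.5 middle (boundaries inclusive), > 1.5 large
copepod_size_class <- function(size_mm) {
  ifelse(size_mm < 0.7, "S", ifelse(size_mm <= 1.5, "M", "L"))
}

#' Assign species to functional groups
#'
#' Deterministic trait-to-group mapping over the closed classification:
#' * rotifers: filter -> RF, carnivore -> RC, algivore -> RP;
#' * copepods/cladocerans: size class (S < 0.7 mm, M 0.7-1.5 mm, L > 1.5 mm;
#'   both boundary values fall in the middle class) crossed with
#'   filter/carnivore -> SCF, SCC, MCF, MCC, LCF, LCC;
#' * protozoans: photosynthetic -> PP, algivore -> PA, bacterivore -> PB,
#'   detritivore -> PD, fungivore -> PF, saprotroph -> PS, raptor -> PR,
#'   omnivore -> PN;
#' * larvae and other taxa -> EXCLUDED, except larvae whose `notes` contain
#'   the token `nauplius`, which join SCF (copepod nauplii are small filter
#'   feeders and are conventionally analysed with that group).
#'
#' @param traits a [trait_table()] (or data.frame coercible to one).
#' @return Named character vector, species_id -> group code, values in
#'   `RF, RC, RP, SCF, SCC, MCF, MCC, LCF, LCC, PP, PA, PB, PD, PF, PS, PR,
#'   PN, EXCLUDED`.
#' @export
assign_functional_group <- function(traits) {
  if (!inherits(traits, "trait_table")) traits <- trait_table(traits)
  n <- nrow(traits)
  out <- character(n)
  for (i in seq_len(n)) {
    cls <- traits$taxon_class[i]
    habit <- traits$feeding_habit[i]
    code <- switch(cls,
      rotifer = unname(ROTIFER_MAP[habit]),
      protozoan = unname(PROTOZOAN_MAP[habit]),
      copepod_cladoceran = {
        suffix <- unname(COPEPOD_MAP[habit])
        if (is.na(suffix)) NA_character_
        else paste0(copepod_size_class(traits$body_size_mm[i]), suffix)
      },
      larva = if (grepl("nauplius", traits$notes[i], ignore.case = TRUE))
        "SCF" else "EXCLUDED",
      other = "EXCLUDED")
    if (is.na(code) || is.null(code))
      stop("no functional group for species '", traits$species_id[i],
           "': taxon_class=", cls, ", feeding_habit=", habit)
    out[i] <- code
  }
  stats::setNames(out, traits$species_id)
}

#' Aggregate a species matrix to functional groups
#'
#' Sums member-species rows per group. EXCLUDED mass is tracked separately
#' so column totals are conserved: `colSums(included) + excluded` equals the
#' species-matrix column sums. Groups of the classification that received
#' no species (or only zero rows) are retained with zero rows and flagged,
#' keeping matrix shapes stable across datasets.
#'
#' @param mat species x sample numeric matrix (see [abundance_matrix()]).
#' @param traits a [trait_table()] covering every species in `mat`.
#' @param drop_empty drop all-zero group rows (default `TRUE`; set `FALSE`
#'   for shape-stable output over the full classification).
#' @return Object of class `group_matrix`: list with `values` (included
#'   group x sample matrix), `excluded` (per-sample excluded mass),
#'   `assignment` (species -> code), `empty_groups`.
#' @export
aggregate_by_group <- function(mat, traits, drop_empty = TRUE) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  assignment <- assign_functional_group(traits)
  missing_sp <- setdiff(rownames(mat), names(assignment))
  if (length(missing_sp) > 0)
    stop("species without trait record: ", paste(missing_sp, collapse = ", "))
  codes <- assignment[rownames(mat)]

  included <- setdiff(GROUP_CODES, "EXCLUDED")
  values <- matrix(0, nrow = length(included), ncol = ncol(mat),
                   dimnames = list(included, colnames(mat)))
  for (g in included) {
    members <- rownames(mat)[codes == g]
    if (length(members) > 0)
      values[g, ] <- colSums(mat[members, , drop = FALSE])
  }
  excl_members <- rownames(mat)[codes == "EXCLUDED"]
  excluded <- if (length(excl_members) > 0)
    colSums(mat[excl_members, , drop = FALSE])
  else stats::setNames(numeric(ncol(mat)), colnames(mat))

  empty <- rownames(values)[rowSums(values) == 0]
  if (drop_empty && length(empty) > 0)
    values <- values[setdiff(rownames(values), empty), , drop = FALSE]

  structure(list(values = values, excluded = excluded,
                 assignment = assignment, empty_groups = empty),
            class = "group_matrix")
}

#' @export
print.group_matrix <- function(x, ...) {
  cat("<group_matrix> ", nrow(x$values), " groups x ", ncol(x$values),
      " samples; excluded mass in ", sum(x$excluded > 0), " samples\n",
      sep = "")
  invisible(x)
}

#' Relative functional-group composition
#'
#' Share of each included group in the included total (EXCLUDED mass never
#' enters the denominator), per sample or pooled per stratum x season.
#' Shares sum to 1 per unit; all-zero units yield `NA` shares and are
#' flagged.
#'
#' @param gm a `group_matrix` from [aggregate_by_group()].
#' @param by `"sample"` (default) or `"stratum_season"` (requires `samples`).
#' @param samples the `samples` table of the source [community_dataset()]
#'   (needed for pooling by stratum x season).
#' @return data.frame with columns `unit`, `group`, `share`.
#' @export
relative_composition <- function(gm, by = c("sample", "stratum_season"),
                                 samples = NULL) {
  stopifnot(inherits(gm, "group_matrix"))
  by <- match.arg(by)
  vals <- gm$values
  if (by == "stratum_season") {
    if (is.null(samples))
      stop("pooling by stratum_season requires the dataset's samples table")
    idx <- match(colnames(vals), samples$sample_id)
    if (anyNA(idx)) stop("samples table does not cover all matrix columns")
    unit <- paste(samples$stratum[idx], samples$season[idx], sep = ":")
    units <- unique(unit)
    pooled <- vapply(units, function(u)
      rowSums(vals[, unit == u, drop = FALSE]), numeric(nrow(vals)))
    vals <- matrix(pooled, nrow = nrow(vals),
                   dimnames = list(rownames(vals), units))
  }
  totals <- colSums(vals)
  share <- sweep(vals, 2, totals, "/")
  share[, totals == 0] <- NA_real_
  out <- data.frame(
    unit = rep(colnames(vals), each = nrow(vals)),
    group = rep(rownames(vals), times = ncol(vals)),
    share = as.vector(share),
    stringsAsFactors = FALSE)
  attr(out, "undefined_units") <- colnames(vals)[totals == 0]
  out
}
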